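# Stylised configuration of the Gilgandra region: 4,101 patient agents,
# 3 primary medical centres and 1 hospital. Demographic marginals are shaped
# on census/health-survey style variables but are stylised, not survey
# reproductions. Distances are abstract planar km within the extent.
name: gilgandra
n_agents: 4101
extent_km: [10, 10]
prevalence:
  undiagnosed: 0.058
  diagnosed: 0.0725
providers:
  - kind: hospital
    location: [5.0, 5.0]
    reputation: 0.66
  - kind: medical_center
    location: [3.8, 5.6]
    reputation: 0.64
  - kind: medical_center
    location: [6.2, 4.2]
    reputation: 0.62
  - kind: medical_center
    location: [5.2, 6.8]
    reputation: 0.60
demographics:
  age: {dist: normal, mean: 46, sd: 18, min: 18, max: 90}
  gender: {male: 0.5, female: 0.5}
  indigenous: 0.14
  ses: {dist: beta, shape1: 3.0, shape2: 3.0}
  education: {dist: beta, shape1: 3.0, shape2: 3.0}
  health_literacy:
    male: {dist: beta, shape1: 2.6, shape2: 3.1}
    female: {dist: beta, shape1: 2.9, shape2: 2.9}
  mental_health: {dist: beta, shape1: 4.0, shape2: 2.5}
  health_behaviors: {dist: beta, shape1: 3.5, shape2: 3.0}
  cultural_beliefs: {dist: beta, shape1: 3.0, shape2: 3.0}
  barriers: {dist: lognormal, meanlog: -0.05, sdlog: 0.65}
  chronic:
    max_conditions: 2
    base_prob: 0.15
    age_coef: 0.004
    severity: {dist: beta, shape1: 2, shape2: 5}
network:
  mean_degree: 8
  rewiring_prob: 0.1
  distance_scale_km: 3
  interaction_prob: 0.2
  churn_monthly_prob: 0.02
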