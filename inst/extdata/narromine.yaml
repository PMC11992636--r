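# Stylised configuration of the Narromine region: 6,190 patient agents,
# 1 medical centre and 1 hospital over a wider extent (the sparser provider
# roster and longer distances drive the region's heavier reliance on
# hospital-based diagnosis).
name: narromine
n_agents: 6190
extent_km: [16, 16]
prevalence:
  undiagnosed: 0.058
  diagnosed: 0.0725
providers:
  - kind: hospital
    location: [8.0, 8.0]
    reputation: 0.68
  - kind: medical_center
    location: [11.0, 11.0]
    reputation: 0.68
demographics:
  age: {dist: normal, mean: 46, sd: 18, min: 18, max: 90}
  gender: {male: 0.5, female: 0.5}
  indigenous: 0.20
  ses: {dist: beta, shape1: 2.8, shape2: 3.2}
  education: {dist: beta, shape1: 2.8, shape2: 3.2}
  health_literacy:
    male: {dist: beta, shape1: 2.6, shape2: 3.1}
    female: {dist: beta, shape1: 2.9, shape2: 2.9}
  mental_health: {dist: beta, shape1: 4.0, shape2: 2.5}
  health_behaviors: {dist: beta, shape1: 3.5, shape2: 3.0}
  cultural_beliefs: {dist: beta, shape1: 3.0, shape2: 3.0}
  barriers: {dist: lognormal, meanlog: 0.15, sdlog: 0.65}
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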