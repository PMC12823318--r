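# Final population PK parameter estimates for inhaled salmeterol and its
# metabolite alpha-hydroxysalmeterol (plasma + urine model).
# Units: volumes L, clearances L/h, rate constants 1/h, urine production L/h.
# IIV entered as CV% of a log-normal random effect: CV% = 100*sqrt(exp(w^2)-1).
# Residual errors are proportional CVs (fractions); correlations are between
# parent and metabolite errors measured in the same sample.
typicals:
  v1_f: 446
  q_f: 1490
  v2_f: 871
  cls_f: 193
  cla_f: 233
  k13: 0.30
  k14: 0.00094
  k35: 0.015
  ur_prod: 0.079
covariates:
  theta_cls_athlete: 1.63
  theta_k14_athlete: 2.91
iiv_cv_percent:
  v1_f: 16
  q_f: 86
  v2_f: 43
  cls_f: 33
  k13: 41
  k14: 29
  ur_prod: 73
ur_prod_iiv_usg_uncorrected_only: true
ruv:
  cv:
    plasma_salm: 0.22
    plasma_metab: 0.38
    urine_salm_low: 0.29
    urine_salm_mid: 0.41
    urine_salm_high: 0.57
    urine_metab_mid: 0.38
    urine_metab_high: 0.51
  corr_plasma: 0.53
  corr_urine: 0.61
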