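# Example configuration for dapapkpd::run_pipeline() / inst/cli/dapapkpd.R.
# Stages run in dependency order; omit any you do not need.
stages: [generate, fit_pk, covsearch, fit_pd, vpc, bootstrap, simulate]
seed: 1
output_dir: pkpd-run
cohort:
  n_subjects: 85
pk: {}            # pk_params() overrides, e.g. theta_cl: 229.3
pd: {}            # pd_params() overrides
fit:
  compute_se: true
vpc:
  n_sim: 1000
bootstrap:
  n_boot: 1000
scenarios:
  doses: [5, 10]
  n_subjects: 1000
  duration: 365
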