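# PRIAS cohort: published HMM point estimates (probability parameters).
# The exit-to-treatment probabilities and log-PSA mixtures below are
# SYNTHETIC illustrative values (not published). They do not enter the
# biopsy-schedule comparison.
pi_nfr: 0.0653
apr: 0.0841
sens: 0.7614
spec: 0.9920
exit_fr_rp: 0.02
exit_fr_norp: 0.04
exit_nfr_rp: 0.05
exit_nfr_norp: 0.04
psa_fr:
  weight: 0.65
  mu1: 1.3
  mu2: 1.9
  sigma1: 0.45
  sigma2: 0.5
psa_nfr:
  weight: 0.55
  mu1: 1.7
  mu2: 2.3
  sigma1: 0.45
  sigma2: 0.55
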