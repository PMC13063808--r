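# Calibrated site parameters behind msn_model()/msn_nh2_model().
# The pK values are fixed a priori (amphoteric silanol couple with
# pK_acid + pK_base = 9.8, so the bare-surface zero-charge point sits at
# pH 4.9; surface-amine pK well below the solution value of a free
# propylamine, as grafted amines on silica are known to be). The
# densities (and the amine pK within [7, 7.6]) were then solved once so
# the package's own forward model in 10 mM Tris at a 7 Angstrom slipping
# plane reproduces the headline observables of bare and
# aminopropyl-grafted mesoporous silica: IEP 4.9 / 7.9 and
# zeta(pH 7.5) = -14 / +10 mV. Synthetic calibration -- placeholders,
# not experimentally fitted site chemistries. See the methods vignette.
.msn_cal <- list(
  pK_acid = 7.6, N_acid = 0.0769,
  pK_base = 2.2, N_base = 0.0769
)

.msn_nh2_cal <- list(
  pK_acid = 7.6,   N_acid = 0.0384,
  pK_base = 2.2,   N_base = 0.0384,
  pK_amine = 7.05, N_amine = 0.206
)
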