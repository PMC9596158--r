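# Re-modelling roster: the 10 algorithm families used alone (no selector
# stage), with the elastic net expanded over 9 alpha values = 18 models.
version: 1
name: remodel
pairing: singles
modelers:
  - family: RSF
  - family: LASSO
  - family: Ridge
  - family: Enet
    alpha: [0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9]
  - family: GBM
  - family: SurvSVM
  - family: SuperPC
  - family: plsRcox
  - family: CoxBoost
  - family: StepCox
    direction: both
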