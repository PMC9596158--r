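# Default combination roster: each of the four selector-capable algorithms
# is paired with every modeler variant except an identical one, giving
# 4 x 20 - 4 = 76 selector + modeler combinations.
version: 1
name: default
pairing: pairs
selectors:
  - family: RSF
  - family: LASSO
  - family: CoxBoost
  - family: StepCox
    direction: both
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
    direction: [both, backward, forward]
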