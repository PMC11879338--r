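seed: 1
anatomy:
  lvEndoRadius: 22.0
  lvEndoLong: 60.0
  lvWall: 10.0
  rvEndoRadius: 18.0
  rvEndoLong: 48.0
  rvWall: 5.0
  septalGap: 2.0
  edgeLength: 6.0
  atrialHeight: 12.0
  electrodeRadius: 120.0
  electrodeHeight: -20.0
  myocardialCV: 0.6
  fastEndoCV: 1.5
  fastEndoRho: 0.15
  atrialCV: 0.8
  interatrialCV: 2.0
  hisOffset: 150.0
  rvotPhiStart: 1.0471976
  rvotExtent: 0.7
  rvotZmin: 0.8
  septalBridgeMax: 15.0
  uccTol: 4.0
  seed: 1
sampling:
  nPerVentricle: 500
  zRange:
  - 0.5
  - 1.0
  phiRange:
  - -3.1415927
  - 3.1415927
  rhoRange:
  - 0.0
  - 1.0
  alphaRange:
  - 0.0
  - 1.0
  gammaRange:
  - -3.1415927
  - 3.1415927
  betaRange:
  - 0.0
  - 1.0
  maxLength: 60.0
  cvap: 2.0
  seed: 1
simulation:
  horizon: 700.0
  period: 1.0
  cutoff: 150.0
  scale: 0.32
sensitivity:
  degree: 3.0
  nRandom: 100.0
exemplar:
  rho: 1.0
  z: 0.53
  phi: -0.49
  ventricle: RV
  tven: 125.0
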