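# Fitted population model for intravenous flunixin in Thoroughbred horses.
# Units: volumes L/kg, clearances L/kg/h, concentrations ng/mL, times h.
# Between-horse variability declared as lognormal CV percent per parameter.
model:
  units:
    volume: L/kg
    clearance: L/kg/h
    concentration: ng/mL
    time: h
  theta:
    V1: 0.149
    V2: 0.012
    V3: 0.029
    CL: 0.047
    CL2: 0.00015
    CL3: 0.00443
    Rss: 36.8
  cv:
    V1: 2.0
    V2: 4.2
    V3: 19.1
    CL: 30.0
    CL2: 14.8
    CL3: 10.3
    Rss: 55.5
  residual:
    plasma:
      add: 0.063   # additive SD, concentration units as declared above
      prop: 0.30   # proportional SD (fraction)
    urine:
      add: 0.080
      prop: 0.30
regimens:
  single:  {dose: 1.1, interval: 24, n_doses: 1}
  q12h_1d: {dose: 1.1, interval: 12, n_doses: 2}
  q24h_5d: {dose: 1.1, interval: 24, n_doses: 5}
  q12h_5d: {dose: 1.1, interval: 12, n_doses: 10}
screening_limits:
  - {label: IFHA-ISL, matrix: plasma, limit: 1}
  - {label: IFHA-ISL, matrix: urine, limit: 100}
  - {label: RMTC, matrix: plasma, limit: 5}
simulation:
  n: 5000
  seed: 20211
  levels: [5, 10, 25, 50, 75, 90, 95]
estimation:
  bootstrap_replicates: 50
  rel_tol: 1.0e-6
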