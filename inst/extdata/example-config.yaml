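# Example lungtrace run configuration. Absent sections fall back to the
# package defaults; units: rates per year, sizes cm^3 unless suffixed,
# intensities in packs per day.
seed: 20240401

smoking:
  p_init:
    male: 0.55
    female: 0.40
  quit_rate: 0.025

tsce:
  male:
    nu0: 0.04
    alpha0: 7
    gamma0: 0.13
    a1: 5
    a2: 1
  female:
    nu0: 0.035
    alpha0: 7
    gamma0: 0.13
    a1: 5
    a2: 1

progression:
  xi: 0.01
  mu_n: 8.05e-9
  mu_m: 2.78e-9
  K: 3.80
  theta: 1.15

detection:
  eta: 1.0e-4
  w0: 0.065
  w1: 1.5e+3
  w2: 7.0e+4
  cycle_years: 1

cohort:
  births:
    start: 1890
    end: 1960
    count: 2877000
  scale: 0.001
  obs_window: [1995, 1999]

estimation:
  n_sim: 20000
  maxit: 300
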