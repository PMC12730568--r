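omega: 2.0
coefficients:
  r1:
    form: sinusoid
    mean: 10.0
    amplitude: 1.0
    angularFrequency: 3.141592653589793
    phase: 0.0
    period: 2.0
  b:
    form: sinusoid
    mean: 4.4
    amplitude: 0.1
    angularFrequency: 3.141592653589793
    phase: 0.0
    period: 2.0
  beta:
    form: sinusoid
    mean: 1.5
    amplitude: 0.1
    angularFrequency: 3.141592653589793
    phase: 0.0
    period: 2.0
  delta:
    form: sinusoid
    mean: 2.0
    amplitude: 0.01
    angularFrequency: 3.141592653589793
    phase: 0.0
    period: 2.0
  c:
    form: sinusoid
    mean: 10.460000000000001
    amplitude: 0.11
    angularFrequency: 3.141592653589793
    phase: 0.0
    period: 2.0
  psi:
    form: sinusoid
    mean: 1.49
    amplitude: 0.99
    angularFrequency: 3.141592653589793
    phase: 0.0
    period: 2.0
  alpha:
    form: sinusoid
    mean: 0.5
    amplitude: 0.01
    angularFrequency: 3.141592653589793
    phase: 0.0
    period: 2.0
  a:
    form: sinusoid
    mean: 0.007
    amplitude: 0.01
    angularFrequency: 3.141592653589793
    phase: 0.0
    period: 2.0
  e:
    form: sinusoid
    mean: 0.04
    amplitude: 0.01
    angularFrequency: 3.141592653589793
    phase: 0.0
    period: 2.0
  gamma:
    form: sinusoid
    mean: 3.65
    amplitude: 0.02
    angularFrequency: 3.141592653589793
    phase: 0.0
    period: 2.0
  r2:
    form: sinusoid
    mean: 0.08
    amplitude: 0.01
    angularFrequency: 3.141592653589793
    phase: 0.0
    period: 2.0
  d:
    form: sinusoid
    mean: 3.85
    amplitude: 0.01
    angularFrequency: 3.141592653589793
    phase: 0.0
    period: 2.0
  D1:
    form: constant
    mean: 1.0
  D2:
    form: constant
    mean: 1.0
  D3:
    form: constant
    mean: 1.0
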