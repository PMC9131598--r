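# Best-supported divergence scenario for the four Aegean regional demes.
# Backward in time: the central-western (CW) deme switches to the small
# ancestral size at t0 (founding bottleneck after its Holocene split;
# interpretation: unresolved), merges into the north-western (NW) deme at
# t2, and at t3 the NW and NE demes merge into the northern (N) deme, which
# takes the ancestral size Na (an effective trifurcation in the Pleistocene).
name: scenario13
# "N" is quoted: bare N is a YAML-1.1 boolean
demes: ["N", NE, NW, CW]
sizes:
  "N": Ne1
  NE: Ne2
  NW: Ne3
  CW: Ne4
priors:
  - {name: Ne1, shape: log-uniform, lower: 10, upper: 1.0e+7}
  - {name: Ne2, shape: log-uniform, lower: 10, upper: 1.0e+7}
  - {name: Ne3, shape: log-uniform, lower: 10, upper: 1.0e+7}
  - {name: Ne4, shape: log-uniform, lower: 10, upper: 1.0e+7}
  - {name: Na,  shape: log-uniform, lower: 10, upper: 1.0e+5}
  - {name: t0,  shape: log-uniform, lower: 10, upper: 1.0e+4}
  - {name: t2,  shape: log-uniform, lower: 10, upper: 1.0e+6}
  - {name: t3,  shape: log-uniform, lower: 10, upper: 2.0e+6}
events:
  - {time: t0, type: size_change, deme: CW, size: Na}   # interpretation: unresolved
  - {time: t2, type: merge, from: CW, to: NW}
  - {time: t3, type: merge, from: NW, to: "N"}
  - {time: t3, type: merge, from: NE, to: "N"}
  - {time: t3, type: size_change, deme: "N", size: Na}
constraints:
  - t0 < t2
  - t2 < t3
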