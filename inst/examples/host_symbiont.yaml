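# Host-symbiont invasion experiment: a neutral host (species A, b = c = 0)
# and a symbiont (species B) whose parasitic wild type exploits b = 0.2 and
# whose mutualistic mutant additionally donates c = 0.3, exploiting the
# host's fecundity for its own survival (p = 0, q = 1) and donating from its
# own fecundity to the host's survival (u = 1, v = 0).
scenario: host_symbiont
seed: 1
rate_mode: corrected
lattice:
  L: 25
experiment:
  equilibration_generations: 1000
  post_generations: 1000
  replicates: 100
  introduction_frequency: 0.04
  targets: [B]
species:
  A:
    parasite: {r: 0.5, d: 0.2}
    mutualist: {r: 0.5, d: 0.2}
  B:
    parasite: {r: 0.5, d: 0.2, b: 0.2, b_prime: 0.2, p: 0.0, q: 1.0}
    mutualist: {r: 0.5, d: 0.2, b: 0.2, b_prime: 0.2, c: 0.3, c_prime: 0.3,
                p: 0.0, q: 1.0, u: 1.0, v: 0.0}
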