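# Packaged alpha-emitter decay data (schema version 1).
# Energies in MeV, half-lives in seconds, intensities per decay (normalized
# at load time). `from_daughter` marks alpha lines emitted by the short-lived
# daughter rather than the parent; `daughter.branch` is the per-decay
# probability of routing through that daughter.
version: 1
nuclides:
- name: At-211
  half_life_s: 25970.4        # 7.214 h
  lines:
  - {energy_MeV: 5.870, intensity: 0.418, from_daughter: false}
  - {energy_MeV: 7.450, intensity: 0.582, from_daughter: true}
  daughter:
    branch: 0.582             # electron capture to Po-211
    half_life_s: 0.516
    diffusible: true
- name: Po-210
  half_life_s: 11955686.4     # 138.376 d
  lines:
  - {energy_MeV: 5.304, intensity: 1.0, from_daughter: false}
  daughter: {branch: 0.0, half_life_s: 0.0, diffusible: false}
- name: Po-213
  half_life_s: 3.72e-06
  lines:
  - {energy_MeV: 8.376, intensity: 0.98, from_daughter: false}
  - {energy_MeV: 7.614, intensity: 0.02, from_daughter: false}
  daughter: {branch: 0.0, half_life_s: 0.0, diffusible: false}
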