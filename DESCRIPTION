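Package: vepdecode
Title: Visual Decoding of Image Classes from Low-Density EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for decoding perceived image classes from
    8-channel visually evoked potentials (VEPs). Simulates class-conditional
    N1-P2 VEP sessions with realistic 1/f and line noise, applies quality
    control (bad-trial masking, zero-phase filtering, z-normalization with
    clamping), classifies 20 image classes with a compact depthwise-separable
    CNN (EEGNet) trained with AdamW and one-cycle scheduling, extracts 512-d
    EEG embeddings with an encoder variant, and reconstructs stimuli with a
    small double-conditioned latent diffusion model (cross-attention plus
    time-step conditioning, PLMS sampling) evaluated by n-way top-1 accuracy
    against an inter-trial null control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    png,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
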