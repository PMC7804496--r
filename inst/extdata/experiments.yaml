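# Experiment configuration: one block per reproduced condition.
#
# Primitive constants per condition: eccentricity (deg), viewing distance
# (cm), monitor pixel pitch (mm/px), center-Gaussian sigma (px) at each
# eccentricity, center-to-surround ratio K, target-alone contrast energy
# mu_t, and the sole behavioral parameter e_alpha.  'printed' holds the
# tabulated derived values (pixels/degree, sigma_t, k_phi) for
# cross-checking; 'sweep' the swept variable(s); 'stimulus' the free
# rendering parameters (sizes the source experiments do not pin down).
#
# Note: the tabulated k_phi values of PL and PS are mutually consistent
# with the k_phi formula only if their e_alpha entries (0.010, 0.025) are
# exchanged; both readings are supported (see reproduceTable1()).

HE:
  family: vernier_lines
  eccentricity_deg: [3.88]
  distance_cm: 75.00
  pixel_pitch_mm: 0.282
  contrast_sigma_px: [0.5541]
  K: 5
  mu_t: 0.020228
  e_alpha: 0.080
  ceiling: 0.85
  printed:
    pixels_per_degree: 46.4177
    sigma_t: 0.0006665
    k_phi: 29.5499
  sweep:
    flanker_count: [0, 2, 4, 8, 16]
    height_factor: [0.5, 1, 2]
  stimulus:
    segment_length_deg: 0.333
    offset_deg: 0.05
    gap_deg: 0.067
    line_width_deg: 0.022
    spacing_deg: 0.25
    target_level: 0.0
    flanker_level: 0.0
    background_level: 0.5
    canvas_deg: [9.0, 3.0]

KA:
  family: landolt_bars
  eccentricity_deg: [5.00]
  distance_cm: 2300.00
  pixel_pitch_mm: 0.282
  contrast_sigma_px: [10.8793]
  K: 5
  mu_t: 0.016057
  e_alpha: 0.032
  ceiling: 0.85
  printed:
    pixels_per_degree: 1423.4770
    sigma_t: 0.0005291
    k_phi: 9.9290
  sweep:
    flank_distance_arcmin: [0.06, 0.12, 0.18, 0.24, 0.30, 0.45, 0.60,
                            0.90, 1.20, 1.80, 2.40, 3.00, 3.60]
  stimulus:
    diameter_arcmin: 6.0
    gap_orientation: 0
    bar_length_factor: 1.0
    target_level: 0.0
    flanker_level: 0.0
    background_level: 0.5
    canvas_deg: [0.37, 0.37]

PA1:
  family: concentric_cs
  eccentricity_deg: [10.00]
  distance_cm: 58.00
  pixel_pitch_mm: 0.282
  contrast_sigma_px: [0.8324]
  K: 5
  mu_t: 0.011640
  e_alpha: 0.030
  ceiling: 0.85
  printed:
    pixels_per_degree: 35.8963
    sigma_t: 0.0003835
    k_phi: 15.7745
  sweep:
    flanker_count: [1]
    gapless: [false, true]
    spacing_deg: [0.35, 0.40, 0.45, 0.50]
  stimulus:
    diameter_deg: 1.25
    gap_orientation: 0
    target_level: 0.0
    flanker_level: 0.0
    background_level: 0.5
    canvas_deg: [7.0, 7.0]

PA5:
  family: concentric_cs
  eccentricity_deg: [10.00]
  distance_cm: 58.00
  pixel_pitch_mm: 0.282
  contrast_sigma_px: [0.8324]
  K: 5
  mu_t: 0.011640
  e_alpha: 0.080
  ceiling: 0.85
  printed:
    pixels_per_degree: 35.8963
    sigma_t: 0.0003835
    k_phi: 58.7319
  sweep:
    flanker_count: [5]
    gapless: [false, true]
    spacing_deg: [0.35, 0.40, 0.45, 0.50]
  stimulus:
    diameter_deg: 1.25
    gap_orientation: 0
    target_level: 0.0
    flanker_level: 0.0
    background_level: 0.5
    canvas_deg: [7.0, 7.0]

PL:
  family: letter_array
  eccentricity_deg: [5.00, 10.00, 15.00, 20.00]
  distance_cm: 55.88
  pixel_pitch_mm: 0.282
  contrast_sigma_px: [0.4956, 0.7620, 1.0688, 1.4252]
  K: 5
  mu_t: 0.012000
  e_alpha: 0.010
  ceiling: 0.85
  printed:
    pixels_per_degree: 34.5843
    sigma_t: 0.0003954
    k_phi: 10.8333
  sweep:
    flank_distance_deg: [0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35, 0.40]
  stimulus:
    letter_height_deg: 0.40
    target_letter: r
    flanker_letter: a
    target_level: 0.5
    flanker_level: 0.5
    background_level: 1.0
    canvas_deg: [3.0, 3.0]

PS:
  family: letter_array
  eccentricity_deg: [5.00, 10.00, 15.00, 20.00]
  distance_cm: 55.88
  pixel_pitch_mm: 0.282
  contrast_sigma_px: [0.4956, 0.7620, 1.0688, 1.4252]
  K: 5
  mu_t: 0.005000
  e_alpha: 0.025
  ceiling: 0.85
  printed:
    pixels_per_degree: 34.5843
    sigma_t: 0.0001648
    k_phi: 9.9999
  sweep:
    flank_distance_deg: [0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35, 0.40]
  stimulus:
    letter_height_deg: 0.20
    target_letter: r
    flanker_letter: a
    target_level: 0.5
    flanker_level: 0.5
    background_level: 1.0
    canvas_deg: [2.0, 2.0]
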