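# Example run configuration. Every value here is a package default, not a
# published constant; omit keys to keep the defaults.
alignment:
  omega_fc_thresh: 20    # deg/s, Full Contact quiescence threshold
  k_fc: 50               # samples, quiescence window (0.1 s at 500 Hz)
  k_y: 400               # samples, pitch-axis summation window (0.8 s)
detector:
  min_roll_time: 0.15    # s, Initial Contact -> Heel Off gate
  omega_heeloff_thresh_y: 15   # deg/s
  omega_threshold_high: 200    # deg/s, Toe Off condition 1
  omega_threshold_low: 150     # deg/s, Toe Off condition 3
  k_to: 25               # samples, strictly-decreasing run
  omega_ref: 300         # deg/s, adaptation reference peak
profile:
  lokomat:
    jerk_min: 150        # m/s^3, initial floating band
    jerk_max: 1500
    min_swing_time: 0.10 # s
  lyra:
    jerk_min: 70
    jerk_max: 800
    min_swing_time: 0.12
simulator:
  cycle_duration: 1.2    # s (1.5 m/s belt speed)
  noise_sd_acc: 0.2      # m/s^2
  noise_sd_gyr: 1        # deg/s
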