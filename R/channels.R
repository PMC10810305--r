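# Canonical channel and condition names shared across modules.

CONDITIONS <- c("BootsOnly", "Unpowered", "Powered", "Deadaptation")
EMG_CHANNELS <- c("emg_sol", "emg_mg", "emg_lg", "emg_ta")
MECH_CHANNELS <- c("ankle_angle", "knee_angle", "hip_angle",
                   "ankle_moment", "knee_moment", "hip_moment",
                   "exo_angle", "grf_v")
MUSCLES <- c("sol", "mg", "lg", "ta")
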