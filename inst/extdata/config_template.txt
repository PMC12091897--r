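# prfield configuration template
# Flat key = value file; '#' starts a comment. Unset keys fall back to the
# package defaults (shown here). Unknown keys are rejected.

# --- model parameters ---------------------------------------------------
# p      = 0.5      # somatic area fraction
# Cm     = 3.0      # membrane capacitance (uF/cm2)
# gc     = 2.1      # soma-dendrite coupling conductance (mS/cm2)
# gL     = 0.1      # leak conductance (mS/cm2)
# gNa    = 30       # sodium conductance (mS/cm2)
# gKDR   = 15       # delayed-rectifier K conductance (mS/cm2)
# gCa    = 10       # calcium conductance (mS/cm2)
# gKAHP  = 0.8      # afterhyperpolarization K conductance (mS/cm2)
# gKC    = 15       # fast Ca-activated K conductance (mS/cm2)
# VNa    = 120      # sodium reversal (mV)
# VCa    = 140      # calcium reversal (mV)
# VK     = -15      # potassium reversal (mV)
# VL     = 0        # leak reversal (mV)
# Vsyn   = 60       # synaptic reversal (mV); stored, unused
# Is     = 0        # somatic injected current (uA/cm2)
# Id     = 0.7      # dendritic injected current (uA/cm2)

# --- DC induced field ---------------------------------------------------
# Ve = 0            # field amplitude (mV)

# --- integration --------------------------------------------------------
# dt = 0.1          # RK4 step (ms)
# duration = 7000   # total simulated time (ms)
# record_stride = 1 # record every n-th step

# --- spike detection / regime classification ----------------------------
# spike_threshold = 20      # mV
# transient_discard = 2000  # ms
# intra_burst_isi_max = 25  # ms
# ibi_cv_max = 0.2
# fast_burst_ibi_max = 100  # ms
# resting_std_max = 0.5     # mV
# block_voltage_min = 25    # mV
# block_dwell_min = 1000    # ms
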