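node,attribute,field,deg_to_px
retina,temporal-step__sec,dt,FALSE
outer-plexiform-layer,center-sigma__deg,opl.sigma_center,TRUE
outer-plexiform-layer,surround-sigma__deg,opl.sigma_surround,TRUE
outer-plexiform-layer,center-tau__sec,opl.tau_center,FALSE
outer-plexiform-layer,surround-tau__sec,opl.tau_surround,FALSE
outer-plexiform-layer,opl-relative-weight,opl.w_surround,FALSE
outer-plexiform-layer,opl-amplification,opl.lambda_opl,FALSE
linear-version,center-sigma__deg,opl.sigma_center,TRUE
linear-version,surround-sigma__deg,opl.sigma_surround,TRUE
linear-version,center-tau__sec,opl.tau_center,FALSE
linear-version,surround-tau__sec,opl.tau_surround,FALSE
linear-version,opl-relative-weight,opl.w_surround,FALSE
linear-version,opl-amplification,opl.lambda_opl,FALSE
contrast-gain-control,bipolar-inert-leaks__Hz,bipolar.g_leak,FALSE
contrast-gain-control,amplification__Hz,bipolar.lambda_bip,FALSE
contrast-gain-control,adaptation-sigma__deg,bipolar.sigma_A,TRUE
contrast-gain-control,adaptation-tau__sec,bipolar.tau_A,FALSE
ganglion-layer,sign,ganglion_on.sign,FALSE
ganglion-layer,bipolar-linear-threshold,ganglion_on.v0,FALSE
ganglion-layer,bipolar-linear-threshold,ganglion_off.v0,FALSE
ganglion-layer,bipolar-amplification__Hz,ganglion_on.lambda_g,FALSE
ganglion-layer,bipolar-amplification__Hz,ganglion_off.lambda_g,FALSE
ganglion-layer,value-at-linear-threshold__Hz,ganglion_on.i0,FALSE
ganglion-layer,value-at-linear-threshold__Hz,ganglion_off.i0,FALSE
spiking-channel,g-leak__Hz,lif.g_l,FALSE
spiking-channel,spike-threshold,lif.v_thresh,FALSE
spiking-channel,v-reset,lif.v_reset,FALSE
spiking-channel,refr-mean__sec,lif.tau_refr,FALSE
spiking-channel,sigma-V,lif.sigma_noise,FALSE
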