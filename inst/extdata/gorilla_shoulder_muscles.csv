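muscle,measured_mass_kg,modelled_volume_cm3,loa_length_cm,is_aggregate
M. deltoideus clavicularis,0.063,65.405,25.434,FALSE
M. deltoideus acromialis,0.166,140.047,21.325,FALSE
M. deltoideus spinalis,0.057,51.387,19.733,FALSE
M. deltoideus (combined),0.286,256.839,NA,TRUE
M. supraspinatus,0.084,79.440,15.539,FALSE
M. infraspinatus,0.105,99.730,15.747,FALSE
Total,0.475,436.008,NA,TRUE
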