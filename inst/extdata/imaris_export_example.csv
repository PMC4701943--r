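Spine ID,Position X,Position Y,Position Z,Compartment,Spine Part Volume,Spine Part Area,Spine Part Length,Spine Max Diameter,Spine Neck Mean Diameter
ap_001,12.1,3.4,155.2,apical_main,0.52,3.1,1.9,0.81,0.29
ap_002,11.8,3.9,161.0,apical_main,0.44,2.8,1.6,0.76,0.31
co_001,54.2,18.3,210.4,apical_collateral,0.21,1.9,2.4,0.55,0.22
co_002,49.8,-22.1,198.7,apical_collateral,0.18,1.7,2.1,,0.2
ba_001,-30.5,41.2,-52.3,basal,0.35,2.4,1.2,0.66,
ba_002,-28.9,44.0,-48.8,basal,0.29,2.2,0.9,0.61,0.27
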