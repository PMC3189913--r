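specimen_id,group,skull_length,CBL,nasal_length,mandible_length,mandible_posterior_height,c1_height,c1_alveolar_length,c1_alveolar_width,p4_length,p4_width,p3_length,p3_width,p2_length,c1_lower_height,c1_lower_alveolar_length,c1_lower_alveolar_width,m1_length,m1_width,p4_lower_length,p3_lower_length,p3_lower_width
BIOPSI00177,Panthera_zdanskyi,264.0,236.3,81.6,167.8,85.4,56.0,24.0,16.7,31.7,17.0,22.0,10.0,5.5,40.5,21.9,13.0,24.6,10.7,21.7,15.4,9.7
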