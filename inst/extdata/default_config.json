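{"seed":20260101,"synthetic":{"n_specimens":40,"base_shape_params":{"ml_halfwidth":28,"dp_halfwidth_dorsal":17,"dp_halfwidth_palmar":25,"se_exponent":2.5,"condyle_radius_lat":4.5,"condyle_radius_med":6,"ridge_height":3,"ridge_palmar_frac":0.6,"groove_depth":1.5,"epiphysis_length":26,"proximal_cutoff":45,"kappa_condyle":8,"kappa_ridge":20},"variance_fractions":[0.5,0.3,0.15],"shape_rms_mm":1,"density_rms":0.08,"point_noise_sd":0.15,"node_noise_sd":0.223606797749979,"density_base":0.7,"density_noise_sd":0.0178885438199983,"cloud_density":0.25,"voxel_spacing":[0.3,0.3,0.6],"phantom_density":800,"ct_ha":1600,"ct_h2o":0,"hu_noise_sd":0,"pose_rot_deg":30,"pose_trans_mm":20,"seed":20260101},"cloud":{"density":0.25},"fitting":{"lattice_shape":[6,6,6],"regularization_weight":3e-06,"smoothing_weight":0.001,"coarse_threshold":0.5,"rms_target":0.3,"max_rounds":10,"variance_keep":0.98},"sampling":{"depth":5,"step":0.25},"model":{"variance_target":0.8,"density_channel":"bmd"},"loo":{"max_components":10}}
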