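location,eval_images,eval_points_per_image,ref_images,ref_points_per_image,ref_total_annotations,image_px,area_cm2
Moorea,200,10,471,200,94200,6240000,2500
Line Islands,200,10,532,100,53200,7100000,5850
Nanwan Bay,200,10,690,50,34260,9980000,1225
Heron Reef,200,10,2597,24,62328,6200000,3250
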