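quantity,value
raw_detections,52909
removed_isolated_singles,710
removed_post_release,102
removed_speed,666
retained_detections,51431
n_animals,19
study_days,722
days_with_any_animal,695
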