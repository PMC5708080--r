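# Built-in plugin manifest: kind<TAB>id<TAB>priority<TAB>entry
# services
sample_type_service	service.sample-types	0	new_sample_type_service
convert_service	service.convert	0	new_convert_service
op_service	service.ops	0	new_op_service
# converters
converter	convert.integer-real	100	conv_integer_widen
converter	convert.string-number	10	conv_string_to_number
converter	convert.string-integer	10	conv_string_to_integer
converter	convert.string-real	10	conv_string_to_real
converter	convert.number-string	10	conv_number_to_string
converter	convert.image-dataset	10	conv_image_to_dataset
converter	convert.dataset-image	10	conv_dataset_to_image
converter	convert.path-dataset	5	conv_path_to_dataset
converter	convert.path-image	5	conv_path_to_image
# ops: element-wise math
op	math.add.image-image	0	opdef_math_add_ii
op	math.add.image-constant	0	opdef_math_add_ic
op	math.add.number-number	0	opdef_math_add_ss
op	math.sub.image-image	0	opdef_math_sub_ii
op	math.sub.image-constant	0	opdef_math_sub_ic
op	math.sub.number-number	0	opdef_math_sub_ss
op	math.mul.image-image	0	opdef_math_mul_ii
op	math.mul.image-constant	0	opdef_math_mul_ic
op	math.mul.number-number	0	opdef_math_mul_ss
op	math.div.image-image	0	opdef_math_div_ii
op	math.div.image-constant	0	opdef_math_div_ic
op	math.div.number-number	0	opdef_math_div_ss
op	math.sqrt.image	0	opdef_math_sqrt_image
op	math.sqrt.array	10	opdef_math_sqrt_array
op	math.sqrt.number	0	opdef_math_sqrt_number
# ops: filters and chained ops
op	filter.gauss	0	opdef_filter_gauss
op	image.dog	0	opdef_image_dog
# ops: statistics
op	stats.sum	0	opdef_stats_sum
op	stats.size	0	opdef_stats_size
op	stats.min	0	opdef_stats_min
op	stats.max	0	opdef_stats_max
op	stats.mean	0	opdef_stats_mean
# ops: structure
op	map.unary	0	opdef_map
op	create.img	0	opdef_create_img
op	identity.image	0	opdef_identity_image
op	identity.number	0	opdef_identity_number
op	eval.expr	0	opdef_eval
# formats
format	format.pgm	0	fmtdef_pgm
format	format.ppm	0	fmtdef_ppm
# module pre-/post-processing chains
preprocessor	preprocess.provided	1000	preproc_provided_binder
preprocessor	preprocess.persisted	800	preproc_persisted_loader
preprocessor	preprocess.active-image	600	preproc_active_image
preprocessor	preprocess.defaults	400	preproc_default_filler
preprocessor	preprocess.required	200	preproc_required_check
postprocessor	postprocess.object-index	200	postproc_object_index
postprocessor	postprocess.display	100	postproc_display
script_language	lang.ndo	0	lang_ndo
# console actions
console	console.headless	100	act_headless
console	console.log-level	100	act_log_level
console	console.run	10	act_run
console	console.op	10	act_op
console	console.info	10	act_info
console	console.help	0	act_help
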