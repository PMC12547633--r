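.datatable.aware <- TRUE

# data.table non-standard-evaluation column names
utils::globalVariables(c("lat_idx", "lon_idx", "mean_intensity", "duration",
                         "start", "year", "pix", ":="))
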