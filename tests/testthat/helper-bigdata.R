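# The full-scale synthetic study (n = 300 images, master seed 0) used by the
# acceptance tests; generated once per session and cached.
big_study_cache <- new.env(parent = emptyenv())

get_big_study <- function() {
  if (!is.null(big_study_cache$study)) return(big_study_cache$study)
  ds <- generate_dataset(300, seed = 0)
  feats <- t(vapply(ds$samples,
                    function(s) extract_features(s$image, s$wound_mask),
                    numeric(54)))
  big_study_cache$study <- list(dataset = ds, features = feats,
                                scores = ds$scores$pwat)
  big_study_cache$study
}
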