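# Shared fixtures: scenes are expensive, so heavy ones are generated once per
# test run and memoised here.

.scene_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .scene_cache)) {
    assign(key, force(expr), envir = .scene_cache)
  }
  get(key, envir = .scene_cache)
}

small_at_params <- function(...) {
  scene_params(
    shape = c(6, 128, 128), n_terminals = 30, n_nuclei = 2,
    nucleus_radius = 9, ...
  )
}

small_at_scene <- function(seed = 7) {
  cached(paste0("at_", seed), generate_array_tomography_scene(small_at_params(), seed = seed))
}

# scene -> normalized stack + masks + detected terminals
run_imaging_front_end <- function(scene) {
  st <- normalize_stack(scene$stack)
  masks <- mask_set(
    make_tissue_mask(st),
    make_nuclear_mask(get_channel(st, "DAPI"))
  )
  tset <- detect_terminals(
    get_channel(st, "YFP"),
    nuclear_mask = masks$nuclei, tissue_mask = masks$tissue
  )
  list(stack = st, masks = masks, terminals = tset)
}

confocal_500 <- function(seed) {
  cached(
    paste0("cf500_", seed),
    generate_confocal_terminal_scene(
      scene_params(shape = c(10, 320, 320), n_terminals = 500),
      seed = seed
    )
  )
}

classified_500 <- function(seed) {
  cached(paste0("cp500_", seed), classify_pipeline(confocal_500(seed)$stack))
}
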