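# shared small-problem helpers; heavy solves are cached for the session

test_spec <- function(elevation = 0) catheter_spec(elevation = elevation)

# compact domain for fast solves: lateral extents below the production
# far-field guideline, so the builder's adequacy warning is expected
test_grid <- function(elevation = 0, spacing = 0.5, extents = c(24, 24, 16),
                      tissue_depth = 8) {
  suppressWarnings(build_domain(test_spec(elevation), spacing, extents,
                                tissue_depth))
}

test_field <- local({
  cache <- new.env(parent = emptyenv())
  function(elevation = 0, spacing = 0.5, ratio = 3.5, extents = c(24, 24, 16),
           tissue_depth = 8, tolerance = 1e-8, far_boundary = "insulated") {
    key <- paste(elevation, spacing, ratio, paste(extents, collapse = "x"),
                 tissue_depth, tolerance, far_boundary, sep = "|")
    if (is.null(cache[[key]])) {
      tab <- material_table(sigma_blood = ratio * 0.2, sigma_myocardium = 0.2)
      cache[[key]] <- suppressWarnings(normalized_field(
        test_spec(elevation), table = tab, spacing = spacing,
        extents = extents, tissue_depth = tissue_depth,
        tolerance = tolerance, far_boundary = far_boundary))
    }
    cache[[key]]
  }
})

# calibrated production-condition model shared by the acceptance tests:
# full 40 x 40 x 35 mm extents at the production 0.25 mm pitch (the
# calibration takes about a minute and is computed once per test run)
acceptance_model <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$cal))
      cache$cal <- calibrate_conductivity_ratio(spacing = 0.25,
                                                tolerance = 1e-7)
    cache$cal
  }
})

acceptance_field_elev2 <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$fm)) {
      cal <- acceptance_model()
      cache$fm <- normalized_field(catheter_spec(elevation = 2),
                                   table = cal$table, spacing = 0.25,
                                   tolerance = 1e-7)
    }
    cache$fm
  }
})
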