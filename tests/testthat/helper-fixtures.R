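# Synthetic materials with prescribed wave speeds (bypassing E/sigma), in
# the same table layout rasterize_model()/fdtd_run() expect.
mk_material <- function(name, rho, cp, cs) {
  data.frame(name = name, E_gpa = NA_real_, sigma = NA_real_, rho = rho,
             c11 = rho * cp^2, c12 = rho * cp^2 - 2 * rho * cs^2,
             c33 = rho * cs^2, c_l = cp, z = rho * cp,
             printed_cl = NA_real_, printed_z = NA_real_, consistent = TRUE,
             stringsAsFactors = FALSE)
}

soft_hard_materials <- function() {
  rbind(mk_material("soft", 1000, 1500, 3),
        mk_material("hard", 1800, 3000, 1500))
}

# plane-wave run through a homogeneous c=1500 block, receiver at depth_mm
homogeneous_run <- function(dx = 0.05, depth_mm = 3, duration = 4e-6) {
  mats <- mk_material("soft", 1000, 1500, 3)
  g <- rasterize_model(layer_stack("soft", 6), dx = dx, width = 1,
                       gap_width = 0, materials = mats, source_mm = 1)
  rec <- data.frame(label = "P", row = as.integer(depth_mm / dx) + 1L,
                    col = g$receivers$col[1])
  fdtd_run(g, source_spec(aperture_mm = "full"), duration = duration,
           pml_cells = 20, receivers = rec)
}

# one shared reduced-resolution fracture-model run per session (expensive)
.run_cache <- new.env(parent = emptyenv())
cached_model_run <- function(gap_width = 4) {
  key <- paste0("gap", gap_width)
  if (is.null(.run_cache[[key]])) {
    cfg <- fracture_model_config(gap_width = gap_width)
    .run_cache[[key]] <- suppressWarnings(run_fracture_model(cfg))
  }
  .run_cache[[key]]
}

# raw sample with exact mean/sd, so summary-based tests can be checked
# against stats::t.test on reconstructed data
raw_with_moments <- function(n, mean, sd, seed) {
  set.seed(seed)
  x <- stats::rnorm(n)
  mean + sd * (x - base::mean(x)) / stats::sd(x)
}
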