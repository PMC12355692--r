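# Model archive: a directory with a JSON manifest (descriptor config,
# training config, seeds, splits) and one JSON weight file per member.

#' Save / load an ensemble potential
#'
#' Writes the ensemble to `dir` as `manifest.json` plus
#' `member_<i>.json` files with full-precision weights, standardization,
#' optimizer state and split indices; `load_hdnnp` reconstructs an
#' identical ensemble (exact double round trip).
#'
#' @param ensemble an `hdnnp_ensemble`.
#' @param dir target directory (created if missing).
#' @return `dir` (or the ensemble for `load_hdnnp`), invisibly.
#' @export
save_hdnnp <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dc <- ensemble$descriptor_config
  manifest <- list(
    n_members = ensemble$n_members, elements = ensemble$elements,
    uncertainty_c = ensemble$uncertainty_c,
    energy_tier = ensemble$energy_tier,
    descriptor_config = list(cutoff = dc$cutoff, radial = dc$radial,
                             angular = dc$angular,
                             element_weights = as.list(dc$element_weights)),
    config = unclass(ensemble$config),
    transfer_log = ensemble$transfer_log)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = I(17), auto_unbox = TRUE)
  for (mi in seq_along(ensemble$members)) {
    m <- ensemble$members[[mi]]
    payload <- list(seed = m$seed, split = m$split,
                    params = m$params, std = m$std, opt = m$opt,
                    history = m$history)
    jsonlite::write_json(payload, file.path(dir,
                                            sprintf("member_%02d.json", mi)),
                         digits = I(17), auto_unbox = TRUE, matrix = "rowmajor")
  }
  invisible(dir)
}

#' @rdname save_hdnnp
#' @export
load_hdnnp <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  dcfg <- descriptor_config(
    cutoff = man$descriptor_config$cutoff,
    radial = as.data.frame(man$descriptor_config$radial),
    angular = as.data.frame(man$descriptor_config$angular),
    element_weights = unlist(man$descriptor_config$element_weights))
  cfg <- do.call(hdnnp_config, man$config[names(man$config) %in%
                                          names(formals(hdnnp_config))])
  fix_param_shapes <- function(p) {
    list(W1 = as.matrix(p$W1), b1 = as.numeric(p$b1),
         W2 = as.matrix(p$W2), b2 = as.numeric(p$b2),
         w3 = as.numeric(p$w3), b3 = as.numeric(p$b3))
  }
  members <- lapply(seq_len(man$n_members), function(mi) {
    raw <- jsonlite::read_json(file.path(dir,
                                         sprintf("member_%02d.json", mi)),
                               simplifyVector = TRUE)
    params <- lapply(raw$params, fix_param_shapes)
    std <- lapply(raw$std, function(s)
      list(mean = as.numeric(s$mean), sd = as.numeric(s$sd)))
    opt <- lapply(raw$opt, function(o)
      list(eta = fix_param_shapes(o$eta),
           prev_grad = fix_param_shapes(o$prev_grad)))
    list(params = params, std = std, opt = opt,
         split = list(train = as.integer(raw$split$train),
                      test = as.integer(raw$split$test)),
         seed = raw$seed,
         history = if (!is.null(raw$history)) as.matrix(raw$history)
                   else NULL)
  })
  ens <- list(members = members, elements = man$elements,
              descriptor_config = dcfg, config = cfg,
              uncertainty_c = man$uncertainty_c,
              energy_tier = man$energy_tier,
              n_members = man$n_members,
              transfer_log = man$transfer_log)
  class(ens) <- "hdnnp_ensemble"
  ens
}
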