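# Extended-XYZ dialect for labeled conformer sets.
#
# Per frame:
#   line 1: atom count
#   line 2: space-separated key=value pairs: energy_tier0=..., energy_tier1=...,
#           energy_tier2=... (kJ/mol) and force_tiers=0,1 naming the tiers
#           whose per-atom force columns follow
#   then one line per atom:
#           element x y z region [fx fy fz per listed force tier]
# Coordinates in Angstrom, forces in kJ/mol/Angstrom; region is the integer
# tag (1 = QM set Q, 2 = represented MM set E').

#' Write a conformer set to extended XYZ
#'
#' @param set a [gen_conformers()] result (class `conformer_set`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(set, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in set$conformers) {
    n <- nrow(cf$coords)
    tiers <- sort(names(cf$forces))
    tier_ids <- sub("tier", "", tiers)
    hdr <- paste(
      paste0(sprintf("energy_%s=%.17g", names(cf$energies), cf$energies),
             collapse = " "),
      paste0("force_tiers=", paste(tier_ids, collapse = ",")))
    writeLines(as.character(n), con)
    writeLines(hdr, con)
    fcols <- do.call(cbind, cf$forces[tiers])
    for (a in seq_len(n)) {
      writeLines(paste(cf$elements[a],
                       paste(sprintf("%.17g", cf$coords[a, ]), collapse = " "),
                       cf$region[a],
                       if (length(tiers))
                         paste(sprintf("%.17g", fcols[a, ]), collapse = " ")
                       else ""), con)
    }
  }
  invisible(path)
}

#' Read a conformer set from extended XYZ
#'
#' @param path file written by [write_extxyz()].
#' @return a `conformer_set` (without the generating config).
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path)
  conformers <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    hdr <- lines[i + 1L]
    kv <- strsplit(strsplit(hdr, "\\s+")[[1]], "=")
    keys <- vapply(kv, `[`, "", 1)
    vals <- vapply(kv, `[`, "", 2)
    energies <- as.numeric(vals[startsWith(keys, "energy_")])
    names(energies) <- sub("energy_", "", keys[startsWith(keys, "energy_")])
    ft <- vals[keys == "force_tiers"]
    tier_ids <- if (length(ft) && nzchar(ft))
      strsplit(ft, ",")[[1]] else character(0)
    body <- lines[i + 1L + seq_len(n)]
    toks <- strsplit(trimws(body), "\\s+")
    elements <- vapply(toks, `[`, "", 1)
    num <- t(vapply(toks, function(tk) as.numeric(tk[-1]),
                    numeric(length(toks[[1]]) - 1L)))
    coords <- num[, 1:3, drop = FALSE]
    region <- as.integer(num[, 4])
    forces <- list()
    for (k in seq_along(tier_ids)) {
      cols <- 4L + (k - 1L) * 3L + 1:3
      forces[[paste0("tier", tier_ids[k])]] <- num[, cols, drop = FALSE]
    }
    conformers[[length(conformers) + 1L]] <-
      list(elements = elements, coords = coords, region = region,
           energies = energies, forces = forces)
    i <- i + 2L + n
  }
  out <- list(conformers = conformers, config = NULL)
  class(out) <- "conformer_set"
  out
}
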