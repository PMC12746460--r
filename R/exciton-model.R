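#' Frenkel exciton model
#'
#' Site-basis electronic Hamiltonian of an array of chromophores: excitation
#' energies `E_A` on the diagonal and electronic couplings `V_AB` off the
#' diagonal.  Only energy differences enter any rate or dissipation
#' expression, so a constant offset of all site energies is irrelevant.
#'
#' @param site_energies Numeric vector of site excitation energies (cm^-1).
#' @param couplings Symmetric coupling matrix (cm^-1) with zero diagonal.
#' @param labels Chromophore names; defaults to names of `site_energies` or
#'   `site1..siteN`.
#' @return An object of class `exciton_model`.
#' @export
exciton_model <- function(site_energies, couplings, labels = NULL) {
  if (!is.numeric(site_energies) || anyNA(site_energies) ||
      any(!is.finite(site_energies))) {
    stop_validation("`site_energies` must be finite numeric")
  }
  n <- length(site_energies)
  couplings <- as.matrix(couplings)
  if (!is.numeric(couplings) || any(!is.finite(couplings)) ||
      nrow(couplings) != n || ncol(couplings) != n) {
    stop_validation(sprintf("`couplings` must be a finite %d x %d numeric matrix", n, n))
  }
  if (max(abs(couplings - t(couplings))) > 1e-9 * max(1, max(abs(couplings)))) {
    stop_validation("`couplings` must be symmetric")
  }
  if (any(diag(couplings) != 0)) {
    stop_validation("`couplings` must have a zero diagonal")
  }
  if (is.null(labels)) {
    labels <- names(site_energies)
    if (is.null(labels)) labels <- paste0("site", seq_len(n))
  }
  if (length(labels) != n) stop_validation("`labels` length must match the number of sites")
  couplings <- (couplings + t(couplings)) / 2
  dimnames(couplings) <- list(labels, labels)
  structure(list(site_energies = stats::setNames(as.numeric(site_energies), labels),
                 couplings = couplings, labels = as.character(labels), n_sites = n),
            class = "exciton_model")
}

#' @export
print.exciton_model <- function(x, ...) {
  cat(sprintf("<exciton_model> %d sites (%s), energy spread %.4g cm^-1\n",
              x$n_sites, paste(x$labels, collapse = ", "),
              diff(range(x$site_energies))))
  invisible(x)
}

site_index <- function(model, site) {
  if (is.character(site)) {
    i <- match(site, model$labels)
    if (is.na(i)) stop_validation(sprintf("unknown site label '%s'", site))
    return(i)
  }
  i <- as.integer(site)
  if (is.na(i) || i < 1L || i > model$n_sites) {
    stop_validation(sprintf("site index %s out of range", as.character(site)))
  }
  i
}

#' Read / write an exciton Hamiltonian matrix file
#'
#' The format is a tab-delimited square matrix with a header row of site
#' labels and a leading label column; diagonal entries are site energies,
#' off-diagonal entries couplings (all cm^-1).  Lines starting with `#` are
#' comments.
#'
#' @param file Path to the matrix file.
#' @return `read_exciton_model()` returns an [exciton_model()];
#'   `write_exciton_model()` returns the path invisibly.
#' @export
read_exciton_model <- function(file) {
  if (!file.exists(file)) stop_validation(sprintf("Hamiltonian file not found: %s", file))
  tab <- utils::read.table(file, header = TRUE, comment.char = "#",
                           row.names = 1, check.names = FALSE, sep = "\t")
  H <- as.matrix(tab)
  if (nrow(H) != ncol(H)) stop_validation("Hamiltonian file must contain a square matrix")
  energies <- diag(H)
  V <- H
  diag(V) <- 0
  exciton_model(energies, V, labels = rownames(H))
}

#' @param model An [exciton_model()] to write.
#' @rdname read_exciton_model
#' @export
write_exciton_model <- function(model, file) {
  H <- model$couplings
  diag(H) <- model$site_energies
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# exciton Hamiltonian (cm^-1): diagonal = site energies, off-diagonal = couplings", con)
  writeLines(paste(c("label", model$labels), collapse = "\t"), con)
  utils::write.table(cbind(model$labels, format(H, digits = 12, trim = TRUE)),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
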