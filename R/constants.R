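#' Physical constants and unit conventions
#'
#' All energies are kcal/mol, lengths are Angstrom (\enc{Å}{A}), times are
#' ps, temperatures K and angles rad throughout the package.
#'
#' @format `kB` is the Boltzmann constant in kcal/(mol K);
#'   `KCAL_PER_AKMA` converts amu \enc{Å}{A}^2/ps^2 to kcal/mol.
#' @name constants
NULL

#' @rdname constants
#' @export
kB <- 0.0019872041

# 1 kcal/mol = 418.4 amu A^2 / ps^2
KCAL_TO_AKMA <- 418.4

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) {
  stop(structure(class = c("wtmetad_parameter_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_degenerate <- function(...) {
  stop(structure(class = c("wtmetad_degeneracy_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_parse <- function(...) {
  stop(structure(class = c("wtmetad_parse_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

as_point_matrix <- function(x, d) {
  if (is.matrix(x)) {
    if (ncol(x) != d) stop_param("expected points with ", d, " column(s)")
    x
  } else {
    if (length(x) %% d != 0L) stop_param("coordinate length not a multiple of ", d)
    matrix(x, ncol = d, byrow = TRUE)
  }
}
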