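#' Physical constants used throughout the package
#'
#' CODATA 2018 exact values. All internal computation is strict SI.
#'
#' @return Named list with elements `R` (molar gas constant, J/(mol K)),
#'   `kB` (Boltzmann constant, J/K), `NA` (Avogadro number, 1/mol) and
#'   `P0` (standard atmosphere, Pa).
#' @export
#' @examples
#' physical_constants()$kB
physical_constants <- function() {
  list(
    R  = 8.314462618,
    kB = 1.380649e-23,
    `NA` = 6.02214076e23,
    P0 = 101325
  )
}

# internal shorthand
.const <- list(
  R  = 8.314462618,
  kB = 1.380649e-23,
  NAv = 6.02214076e23,
  P0 = 101325
)

stop_domain <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "dropnuc_error")))
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(sprintf("`%s` must be a single finite number", name),
                "dropnuc_validation")
  if (positive && x <= 0)
    stop_domain(sprintf("`%s` must be > 0", name), "dropnuc_validation")
  if (nonneg && x < 0)
    stop_domain(sprintf("`%s` must be >= 0", name), "dropnuc_validation")
  invisible(x)
}
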