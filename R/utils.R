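#' Round half away from zero
#'
#' Reporting convention for percentages: ordinary commercial rounding rather
#' than the IEC half-to-even rule used by [base::round()], so that e.g.
#' `82.35 -> 82.4`.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(82.35, -82.35, 4.337), 1)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# classed abort helpers; error classes are part of the package contract
tmt_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "tmtde_error"))
}

format_error <- function(message) tmt_abort(message, "tmtde_format_error")
design_error <- function(message) tmt_abort(message, "tmtde_design_error")
input_error <- function(message) tmt_abort(message, "tmtde_input_error")
config_error <- function(message) tmt_abort(message, "tmtde_config_error")

geo_mean <- function(x) exp(mean(log(x)))

`%||%` <- rlang::`%||%`
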