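# small shared utilities; collates first

# single place for the agroforestry-system labels: high / medium / low
# transmitted radiation
AF_LEVELS <- c("H_PAR", "M_PAR", "L_PAR")

#' Agroforestry system labels
#'
#' The three shade arrangements the package models: `H_PAR` (sparse shade,
#' high transmitted radiation), `M_PAR` (medium) and `L_PAR` (dense
#' multistrata shade, low transmitted radiation).
#'
#' @return Character vector of the three labels, in conventional order.
#' @export
af_levels <- function() AF_LEVELS

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sapflux <- function(msg, class = "sapflux_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}
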