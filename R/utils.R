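#' @keywords internal
"_PACKAGE"

# month labels: one pre-departure baseline plus nine expedition months
.MONTHS <- c("Feb", "Mar", "Apr", "May", "Jun", "Jul", "Aug", "Sep", "Oct")
.MONTH_LABELS <- c("BASELINE", .MONTHS)

#' Expedition month labels
#'
#' The ordered expedition month labels (February through October) used
#' throughout the package, and the full label set including \code{"BASELINE"}.
#'
#' @return Character vector of month labels.
#' @export
expedition_months <- function() .MONTHS

.stop2 <- function(msg, class, call. = FALSE) {
  stop(structure(class = c(class, "icehrv_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == as.integer(x)

.is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1

.month_factor <- function(x, baseline = FALSE) {
  lev <- if (baseline) .MONTH_LABELS else .MONTHS
  bad <- setdiff(unique(as.character(x)), lev)
  if (length(bad))
    stop("invalid month label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  factor(as.character(x), levels = lev)
}

# run code with a locally seeded RNG, restoring the caller's stream
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
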