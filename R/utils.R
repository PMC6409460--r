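#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort %||% .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats rnorm rbinom runif rbeta phyper p.adjust setNames var cov sd
#' @importFrom utils head tail
NULL

# argument checking helpers -------------------------------------------------

stop_bad_arg <- function(msg) abort(msg, class = "ssgwaspath_argument_error")
stop_structural <- function(msg) abort(msg, class = "ssgwaspath_structural_error")
stop_computational <- function(msg) abort(msg, class = "ssgwaspath_computational_error")

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop_bad_arg(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok) {
    stop_bad_arg(sprintf("`%s` must be a single probability in %s0,1%s",
                         name, if (open_left) "(" else "[",
                         if (open_right) ")" else "]"))
  }
  as.numeric(x)
}

is_spd <- function(m, tol = 1e-10) {
  if (!isSymmetric(unname(m), tol = 1e-8)) return(FALSE)
  ev <- eigen(symmpart_dense(m), symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev), 1))
}

symmpart_dense <- function(m) (m + t(m)) / 2

trait_names <- function(n_traits = 3L) {
  if (n_traits == 3L) c("MY", "FY", "AFC") else paste0("trait", seq_len(n_traits))
}
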