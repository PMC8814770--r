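#' Classic triangulation number T0
#'
#' The classic Caspar-Klug triangulation number counts the number of
#' quasi-equivalent positions on an icosahedral capsid surface:
#' \eqn{T_0(h,k) = h^2 + hk + k^2}, where \eqn{(h,k)} are the lattice steps
#' between neighbouring pentamers. A capsid with classic T-number
#' \eqn{T_0} is built from \eqn{60 T_0} major capsid proteins.
#'
#' @param h,k Non-negative integer lattice steps; `(0,0)` is not a capsid.
#' @return Integer `h^2 + h*k + k^2` (vectorized over `h` and `k`).
#' @examples
#' t0_number(1, 0)  # 1
#' t0_number(2, 1)  # 7
#' @export
t0_number <- function(h, k) {
  if (length(h) != length(k)) stop("h and k must have equal length")
  if (any(h < 0) || any(k < 0)) stop("h and k must be non-negative")
  if (any(h != round(h)) || any(k != round(k))) stop("h and k must be integers")
  if (any(h == 0 & k == 0)) stop("(h, k) = (0, 0) is not a valid lattice")
  as.integer(h^2 + h * k + k^2)
}

#' Generalized T-number for hexagonal and trihexagonal lattices
#'
#' Tailed-phage capsid proteins organize on either a hexagonal lattice
#' (major capsid proteins only, \eqn{T = T_0}) or a trihexagonal lattice,
#' where \eqn{60 T_0} minor capsid proteins inserted as trimers add surface
#' so that \eqn{T = 4/3\, T_0}. The 4/3 factor is why fractional T-numbers
#' such as 1.33, 5.33 and 9.33 occur.
#'
#' @inheritParams t0_number
#' @param lattice `"hexagonal"` or `"trihexagonal"`.
#' @return Numeric T-number; exactly `t0` for hexagonal, `4/3 * t0` for
#'   trihexagonal. Use [format_t()] for the conventional 2-decimal display.
#' @examples
#' t_number(1, 0, "trihexagonal")  # 4/3, printed as 1.33
#' t_number(2, 1, "hexagonal")     # 7 (phage HK97)
#' @export
t_number <- function(h, k, lattice = c("hexagonal", "trihexagonal")) {
  lattice <- match.arg(lattice)
  t0 <- t0_number(h, k)
  if (lattice == "hexagonal") as.numeric(t0) else 4 * t0 / 3
}

#' Format a T-number for display
#'
#' Integer T-values print without decimals; fractional (trihexagonal)
#' values print with two decimals (1.33, 5.33, 9.33, ...). The sentinel
#' label `"elongated"` is passed through unchanged.
#'
#' @param t Numeric T-number(s) or the character `"elongated"`.
#' @return Character vector.
#' @export
format_t <- function(t) {
  if (is.character(t)) {
    num <- suppressWarnings(as.numeric(t))
    out <- t
    ok <- !is.na(num)
    out[ok] <- format_t(num[ok])
    return(out)
  }
  ifelse(abs(t - round(t)) < 1e-9,
         formatC(round(t), format = "d"),
         formatC(t, format = "f", digits = 2))
}

#' Enumerate icosahedral capsid architectures
#'
#' Enumerates all distinct (T-number, lattice) pairs with T-value up to
#' `t_max`, each represented by one canonical set of lattice steps
#' (h >= k >= 0, smallest h then smallest k; chiral pairs are not
#' distinguished). T-values realizable on both lattices (e.g. T = 4,
#' T = 12) appear once per lattice.
#'
#' @param t_max Largest T-value to include (>= 1). The default 60 covers
#'   T = 52, the largest architecture observed in high-resolution
#'   structures, with margin for assignment intervals.
#' @return A data.frame of class `capsid_architectures` with columns
#'   `t_value`, `lattice`, `h`, `k`, `t0`, `mcp_count`, `minor_count`,
#'   ordered by `t_value` then lattice. `mcp_count = 60 * t0` for both
#'   lattices; `minor_count = 60 * t0` for trihexagonal lattices, else 0.
#' @examples
#' enumerate_architectures(t_max = 10)
#' @export
enumerate_architectures <- function(t_max = 60) {
  if (!is.numeric(t_max) || length(t_max) != 1 || t_max < 1) {
    stop("t_max must be a single number >= 1")
  }
  hk_max <- ceiling(sqrt(t_max)) + 1L
  grid <- expand.grid(h = 0:hk_max, k = 0:hk_max)
  grid <- grid[grid$h >= grid$k & !(grid$h == 0 & grid$k == 0), ]
  grid$t0 <- as.integer(grid$h^2 + grid$h * grid$k + grid$k^2)
  # canonical representative per t0: smallest h, then smallest k
  grid <- grid[order(grid$t0, grid$h, grid$k), ]
  grid <- grid[!duplicated(grid$t0), ]

  rows <- function(lat) {
    tv <- if (lat == "hexagonal") as.numeric(grid$t0) else 4 * grid$t0 / 3
    keep <- tv <= t_max + 1e-9
    data.frame(
      t_value = tv[keep],
      lattice = rep(lat, sum(keep)),
      h = grid$h[keep], k = grid$k[keep], t0 = grid$t0[keep],
      mcp_count = 60L * grid$t0[keep],
      minor_count = if (lat == "trihexagonal") 60L * grid$t0[keep] else 0L,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(rows("hexagonal"), rows("trihexagonal"))
  out <- out[order(out$t_value, out$lattice), ]
  rownames(out) <- NULL
  class(out) <- c("capsid_architectures", "data.frame")
  out
}
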