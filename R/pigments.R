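# Xanthophyll-cycle and pigment-ratio indices.

#' Xanthophyll (VAZ) pool size
#'
#' Sum of violaxanthin, antheraxanthin and zeaxanthin contents.  When a
#' pre-tabulated pool is supplied it is checked against the component sum
#' (flagged when they disagree by more than \code{tol}, a rounding
#' tolerance) and, with \code{prefer_tabulated = TRUE}, returned instead of
#' the sum -- tabulated pools are typically computed before the components
#' were rounded, so ratios printed alongside them reproduce only from the
#' pool itself.
#'
#' @param V,A,Z Component contents (ug cm-2).
#' @param pool Optional pre-tabulated pool (ug cm-2).
#' @param prefer_tabulated Use the supplied pool when available.
#' @param tol Relative disagreement above which a warning is raised.
#' @return Pool size (ug cm-2), vectorised.
#' @export
vaz_pool <- function(V, A, Z, pool = NULL, prefer_tabulated = TRUE,
                     tol = 0.05) {
  if (any(c(V, A, Z) < 0)) stop("pigment contents must be >= 0")
  s <- V + A + Z
  if (is.null(pool)) return(s)
  bad <- pool > 0 & abs(pool - s) / pool > tol
  if (any(bad))
    warning("tabulated pool differs from V+A+Z by > ", tol * 100,
            "% for ", sum(bad), " leaf/leaves")
  if (prefer_tabulated) pool else s
}

#' Xanthophyll de-epoxidation state
#'
#' \deqn{DES = (A + Z) / (V + A + Z)}
#' indexes engagement of the xanthophyll cycle (violaxanthin de-epoxidase
#' activity); lies in [0, 1] when the pool equals the component sum.
#'
#' @param A,Z Antheraxanthin and zeaxanthin contents (ug cm-2).
#' @param pool VAZ pool size (ug cm-2).
#' @return De-epoxidation state (dimensionless), vectorised.
#' @export
de_epoxidation_state <- function(A, Z, pool) {
  if (any(pool <= 0)) stop("division error: pool must be > 0")
  (A + Z) / pool
}

#' VAZ pool per unit chlorophyll
#'
#' @param pool VAZ pool (ug cm-2).
#' @param chl Chlorophyll content (ug cm-2).
#' @return Dimensionless ratio, vectorised.
#' @export
vaz_per_chl <- function(pool, chl) {
  if (any(chl <= 0)) stop("division error: chl must be > 0")
  pool / chl
}

#' Pigment indices for a table of leaves
#'
#' Computes the VAZ pool, de-epoxidation state and pool-per-chlorophyll
#' ratio for each row of a leaf-scalar table (columns \code{violaxanthin},
#' \code{antheraxanthin}, \code{zeaxanthin}, \code{chl}, optionally
#' \code{vaz_pool_tab}).
#'
#' @param scalars Data frame of per-leaf pigment contents.
#' @param prefer_tabulated Passed to \code{\link{vaz_pool}}.
#' @return Data frame with \code{leaf_id}/\code{treatment} (when present),
#'   \code{vaz_pool}, \code{dep_state}, \code{vaz_per_chl}.
#' @export
pigment_indices <- function(scalars, prefer_tabulated = TRUE) {
  pool <- vaz_pool(scalars$violaxanthin, scalars$antheraxanthin,
                   scalars$zeaxanthin, pool = scalars$vaz_pool_tab,
                   prefer_tabulated = prefer_tabulated)
  out <- data.frame(vaz_pool = pool,
                    dep_state = de_epoxidation_state(
                      scalars$antheraxanthin, scalars$zeaxanthin, pool),
                    vaz_per_chl = vaz_per_chl(pool, scalars$chl))
  keys <- intersect(c("leaf_id", "treatment"), names(scalars))
  if (length(keys)) out <- cbind(scalars[keys], out)
  out
}
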