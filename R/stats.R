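#' Per-scale Mann-Whitney comparison of two cohorts of profiles
#'
#' At each scale (and simplex dimension `k`, when profiles carry several),
#' collects the defined per-subject entropy values of the two groups, drops
#' undefined entries, and runs a two-sided Mann-Whitney U (Wilcoxon
#' rank-sum) test. The exact null distribution is used when both groups have
#' at most 8 defined values and no ties occur; otherwise the normal
#' approximation with continuity and tie correction. No multiple-testing
#' correction is applied across scales: the per-scale p-values are reported
#' raw, to be judged against a single threshold such as 0.05.
#'
#' @param group_a,group_b Lists of [scale_profile][ms_scae] objects, one per
#'   subject, computed with the same method and scale range.
#' @param k Simplex dimension(s) to compare; default all shared.
#' @param labels Character pair naming the groups.
#'
#' @return A `group_comparison` tibble: `scale`, `k`, `u_statistic`
#'   (pairs where group A exceeds group B), `p_value`, `n1`, `n2` (defined
#'   counts per group). Scales where either group has no defined value get
#'   `NA` statistics.
#' @export
compare_groups <- function(group_a, group_b, k = NULL,
                           labels = c("A", "B")) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  a_tab <- dplyr::bind_rows(purrr::map(group_a, tidy), .id = "subject")
  b_tab <- dplyr::bind_rows(purrr::map(group_b, tidy), .id = "subject")
  ks <- if (is.null(k)) unique(a_tab$k) else k
  grid <- tidyr_expand(unique(a_tab$scale), ks)
  rows <- purrr::pmap(grid, function(scale, k) {
    va <- pick_values(a_tab, scale, k)
    vb <- pick_values(b_tab, scale, k)
    res <- mann_whitney(va, vb)
    tibble::tibble(scale = scale, k = k, u_statistic = res$u, p_value = res$p,
                   n1 = length(va), n2 = length(vb))
  })
  structure(
    tibble::new_tibble(dplyr::bind_rows(rows), labels = labels,
                       class = "group_comparison"),
    class = c("group_comparison", class(tibble::tibble())))
}

tidyr_expand <- function(scales, ks) {
  tibble::tibble(scale = rep(sort(scales), each = length(ks)),
                 k = rep(ks, times = length(scales)))
}

pick_values <- function(tab, s, kk) {
  sel <- tab$scale == s & (tab$k %in% kk | (is.na(kk) & is.na(tab$k))) & tab$defined
  tab$entropy[sel]
}

# two-sided Mann-Whitney U; exact for small tie-free samples
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    return(list(u = NA_real_, p = NA_real_))
  }
  exact <- length(a) <= 8 && length(b) <= 8 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact, correct = TRUE)
  )
  list(u = unname(wt$statistic), p = min(wt$p.value, 1))
}

#' @export
print.group_comparison <- function(x, ...) {
  lb <- attr(x, "labels")
  cat(sprintf("<group_comparison> %s vs %s\n", lb[1], lb[2]))
  NextMethod()
}

#' @exportS3Method generics::tidy
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' Export a group comparison table to CSV
#'
#' @param comparison A `group_comparison`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparison, path) {
  utils::write.csv(tidy(comparison), path, row.names = FALSE)
  invisible(path)
}
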