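# Two-dimensional embedding of non-pregnancy diagnosis profiles and
# rank-sum comparison of coordinate distributions between patient groups.

#' Embed patients' diagnosis profiles in two dimensions
#'
#' Runs UMAP on the binary presence matrix. The matrix must not contain
#' diagnoses in the "pregnancy complications" category (use
#' [drop_category()] first) so the layout reflects diagnoses leading to
#' the outcome rather than indicating it. Deterministic given `seed` and
#' input; hyperparameters are recorded in the result's `metadata`
#' attribute.
#'
#' @param pm `phenome_matrix` with pregnancy-complication columns removed.
#' @param seed RNG seed.
#' @param n_neighbors,min_dist,metric UMAP hyperparameters (common
#'   defaults; clamped to the data size where necessary).
#' @return data frame (`embedding_result`): `person_id`, `dim1`, `dim2`,
#'   `group`, `stratum` (age <35 / 35+).
#' @export
embed_patients <- function(pm, seed = 42, n_neighbors = 15, min_dist = 0.1,
                           metric = "euclidean") {
  if (any(tolower(pm$diagnoses$category) == "pregnancy complications")) {
    stop("matrix still contains 'pregnancy complications' diagnoses; ",
         "call drop_category() before embedding", call. = FALSE)
  }
  n <- nrow(pm$presence)
  if (n < 4L) stop("need at least 4 patients to embed", call. = FALSE)
  nn <- max(2L, min(n_neighbors, n - 1L))
  set.seed(seed)
  coords <- tryCatch(
    uwot::umap(pm$presence, n_neighbors = nn, min_dist = min_dist,
               metric = metric, n_threads = 1, n_sgd_threads = 0),
    error = function(e) {
      # degenerate inputs (e.g. identical rows) can break spectral
      # initialization; retry with random init
      set.seed(seed)
      uwot::umap(pm$presence, n_neighbors = nn, min_dist = min_dist,
                 metric = metric, n_threads = 1, n_sgd_threads = 0,
                 init = "random")
    }
  )
  stopifnot(all(is.finite(coords)))
  out <- data.frame(
    person_id = pm$patients$person_id,
    dim1 = coords[, 1], dim2 = coords[, 2],
    group = pm$patients$group,
    stratum = ifelse(pm$patients$age_at_index < 35, "under35", "over35"),
    stringsAsFactors = FALSE
  )
  attr(out, "metadata") <- list(seed = seed, n_neighbors = nn,
                                min_dist = min_dist, metric = metric)
  class(out) <- c("embedding_result", "data.frame")
  out
}

#' Wilcoxon rank-sum tests on embedding coordinates
#'
#' Two-sided rank-sum test of each embedding dimension between the two
#' label groups; both dimensions are reported.
#'
#' @param coords matrix or data frame with columns `dim1`, `dim2`.
#' @param labels two-level grouping vector.
#' @return data frame with `dimension`, `p`, and the two group labels.
#' @export
ranksum_by_group <- function(coords, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels", call. = FALSE)
  g1 <- levels(labels)[1]
  p <- vapply(c("dim1", "dim2"), function(d) {
    x <- coords[[d]][labels == g1]
    y <- coords[[d]][labels != g1]
    stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE)$p.value
  }, numeric(1))
  data.frame(dimension = c("dim1", "dim2"), p = unname(p),
             group1 = g1, group2 = levels(labels)[2],
             stringsAsFactors = FALSE)
}
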