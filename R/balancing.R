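#' Per-class generation counts for a balancing mode
#'
#' Balance modes generate `n_major - n_minor` minority rows (no majority
#' rows). Expand mode targets `T = n_major + round(multiplier * n_major)`
#' samples per class (round-half-up), generating `T - n_minor` minority and
#' `T - n_major` majority rows; `multiplier = 1` doubles the majority count.
#'
#' @param n_minor,n_major Class sample counts (`n_minor <= n_major`).
#' @param mode One of `"gan_balance"`, `"gan_expand"`, `"smote"`,
#'   `"random_oversample"`.
#' @param multiplier Expansion multiplier in (0, 1], expand mode only.
#' @return A list `c(minor = , major = )` of generation counts.
#' @export
target_counts <- function(n_minor, n_major,
                          mode = c("gan_balance", "gan_expand", "smote",
                                   "random_oversample"),
                          multiplier = 1.0) {
  mode <- match.arg(mode)
  assert_that(n_minor > 0 && n_major > 0, "class counts must be positive")
  assert_that(n_minor <= n_major, "n_minor must not exceed n_major")
  if (mode == "gan_expand") {
    assert_that(multiplier > 0 && multiplier <= 1,
                "multiplier must be in (0, 1] for expand mode")
    target <- n_major + round_half_up(multiplier * n_major)
    c(minor = as.integer(target - n_minor), major = as.integer(target - n_major))
  } else {
    c(minor = as.integer(n_major - n_minor), major = 0L)
  }
}

# SMOTE-style rows: each synthetic row lies on the segment between a minority
# row and one of its k nearest minority neighbours (Euclidean distance).
smote_rows <- function(minority, n_new, k = 5) {
  n <- nrow(minority)
  assert_that(n >= 2, "SMOTE needs at least 2 minority samples")
  k <- min(k, n - 1)
  d <- as.matrix(stats::dist(minority))
  diag(d) <- Inf
  # k nearest neighbour indices per row
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  base <- sample.int(n, n_new, replace = TRUE)
  pick <- nn[cbind(base, sample.int(k, n_new, replace = TRUE))]
  gap <- stats::runif(n_new)
  minority[base, , drop = FALSE] +
    gap * (minority[pick, , drop = FALSE] - minority[base, , drop = FALSE])
}

#' Balance (or expand) a labeled dataset
#'
#' Returns the original rows plus synthetic rows so that both classes reach
#' the counts implied by [target_counts()]. GAN modes draw from the per-class
#' generators of a trained [retrain_class_gans()] pair and inverse-transform
#' to the original feature scale; `"smote"` interpolates between minority
#' nearest neighbours; `"random_oversample"` duplicates minority rows with
#' replacement.
#'
#' @param real A [labeled_matrix()] with two classes.
#' @param mode Balancing mode, see [target_counts()].
#' @param gans A `class_gan_pair` (required for the GAN modes).
#' @param transformer The [fit_transformer()] used on the real data (GAN
#'   modes; generated rows are inverse-transformed with it).
#' @param multiplier Expansion multiplier (expand mode).
#' @param k SMOTE neighbour count (default 5, auto-reduced when the minority
#'   class is small).
#' @param seed Optional seed; balancing is deterministic given the seed.
#' @return A [labeled_matrix()] with equal class counts; original rows come
#'   first, unchanged.
#' @export
apply_balancing <- function(real,
                            mode = c("gan_balance", "gan_expand", "smote",
                                     "random_oversample"),
                            gans = NULL, transformer = NULL, multiplier = 1.0,
                            k = 5, seed = NULL) {
  mode <- match.arg(mode)
  assert_that(!is.null(real$labels), "real data must be labeled")
  counts <- table(real$labels)
  assert_that(length(counts) == 2, "real data must contain exactly two classes")
  if (!is.null(seed)) set.seed(seed)
  minor_class <- names(counts)[which.min(counts)]
  major_class <- setdiff(names(counts), minor_class)
  n_minor <- counts[[minor_class]]
  n_major <- counts[[major_class]]
  tc <- target_counts(n_minor, n_major, mode, multiplier)

  synth_for <- function(class_name, n_new) {
    if (n_new == 0) return(NULL)
    if (mode %in% c("gan_balance", "gan_expand")) {
      assert_that(!is.null(gans), "GAN modes require a trained class_gan_pair")
      side <- if (class_name == gans$under_class) gans$under else gans$over
      gen <- generate_samples(side$generator, n_new, transformer = transformer)
      vals <- gen$values
      colnames(vals) <- real$feature_names
      vals
    } else if (mode == "smote") {
      minority <- real$values[real$labels == class_name, , drop = FALSE]
      smote_rows(minority, n_new, k = k)
    } else {
      minority <- real$values[real$labels == class_name, , drop = FALSE]
      minority[sample.int(nrow(minority), n_new, replace = TRUE), , drop = FALSE]
    }
  }

  new_minor <- synth_for(minor_class, tc[["minor"]])
  new_major <- synth_for(major_class, tc[["major"]])
  values <- rbind(real$values, new_minor, new_major)
  labels <- c(real$labels,
              rep(minor_class, tc[["minor"]]),
              rep(major_class, tc[["major"]]))
  labeled_matrix(values, labels = labels, feature_names = real$feature_names)
}
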