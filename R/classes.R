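#' Functional class enrichment under a label-permutation null
#'
#' Counts, per single-letter functional class (COG-style), the members of the
#' focal stratum annotated with that class; a protein carrying several codes
#' contributes one count to each of its classes. The default null permutes
#' the multiset of class codes across the annotated universe proteins while
#' preserving each protein's number of codes, so per-protein code counts and
#' global per-class totals are conserved exactly in every draw.
#' `null = "marginal"` instead resamples each code independently from the
#' marginal code distribution.
#'
#' @param annotation A `class_annotation` (protein -> codes).
#' @param universe Character vector of proteins defining the background
#'   (typically the annotated network proteins).
#' @param focal Character vector of proteins, a subset of `universe`, with at
#'   least one annotated member.
#' @param reps Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param null `"permute"` (default) or `"marginal"`.
#' @return A `class_enrichment_table` data frame with one row per class:
#'   `class`, `observed`, `null_mean`, `null_sd`, `ratio`, `p_ge`, `p_le`.
#' @export
class_enrichment <- function(annotation, universe, focal, reps = 10000,
                             seed = NULL, null = c("permute", "marginal")) {
  null <- match.arg(null)
  stopifnot(inherits(annotation, "class_annotation"))
  universe <- as.character(universe); focal <- as.character(focal)
  if (!all(focal %in% universe)) stop("focal must be a subset of the universe")
  ann <- annotation[intersect(names(annotation), universe)]
  if (length(ann) == 0L) stop("annotation covers no universe protein")
  if (length(intersect(focal, names(ann))) == 0L) {
    stop("focal stratum has no annotated member")
  }
  owner <- rep(names(ann), lengths(ann))
  codes <- unlist(ann, use.names = FALSE)
  classes <- sort(unique(codes))
  code_f <- factor(codes, levels = classes)
  in_focal <- owner %in% focal
  observed <- as.integer(table(code_f[in_focal]))
  nslot <- length(codes)
  draws <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      perm <- if (null == "permute") {
        code_f[sample.int(nslot)]
      } else {
        code_f[sample.int(nslot, nslot, replace = TRUE)]
      }
      as.integer(table(perm[in_focal]))
    }, integer(length(classes)))
  })
  draws <- matrix(draws, nrow = length(classes))
  null_mean <- rowMeans(draws)
  out <- data.frame(
    class = classes,
    observed = observed,
    null_mean = null_mean,
    null_sd = apply(draws, 1L, stats::sd),
    ratio = ifelse(null_mean > 0, observed / null_mean, NA_real_),
    p_ge = (1 + rowSums(draws >= observed)) / (1 + reps),
    p_le = (1 + rowSums(draws <= observed)) / (1 + reps)
  )
  structure(out, class = c("class_enrichment_table", "data.frame"),
            n_randomizations = reps, seed = seed, null = null,
            n_focal_annotated = length(intersect(focal, names(ann))))
}
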