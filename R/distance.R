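#' Mixed-data distance matrix with pairwise deletion of missing scores
#'
#' Builds a specimen-by-specimen dissimilarity matrix from a collapsed
#' numeric score table, handling missing (inapplicable) cells by pairwise
#' deletion: each pair of specimens is compared only on the characters both
#' were scored for.
#'
#' Two metrics are available:
#' \describe{
#'   \item{`gower`}{Gower's coefficient for ordered characters: per
#'     character, \eqn{|x - y| / r} with \eqn{r} the character's range,
#'     averaged over the jointly observed characters. Distances lie in
#'     \[0, 1\]. `range_mode = "observed"` takes \eqn{r} as the observed
#'     column range (max minus min over non-missing entries);
#'     `"theoretical"` uses the span of the character's allowed states.
#'     Characters with zero observed range carry no information and are
#'     dropped from the computation with a warning.}
#'   \item{`euclidean`}{Euclidean distance on the raw collapsed scores with
#'     the classical pairwise-deletion rescaling
#'     \eqn{\sqrt{(p/m)\sum (x-y)^2}}, where the sum runs over the \eqn{m}
#'     jointly observed of \eqn{p} characters (the convention of
#'     [stats::dist()]).}
#' }
#'
#' @param x A `numeric_scores` tibble from [collapse_multistate()], or a
#'   numeric matrix/data frame of specimens by characters with rownames.
#' @param metric `"gower"` (default) or `"euclidean"`.
#' @param range_mode For `metric = "gower"`: `"observed"` (default) or
#'   `"theoretical"`.
#' @return A [stats::dist] object with specimen labels.
#' @examples
#' d <- melanoides_shell_scores() |> collapse_multistate() |> mixed_distance()
#' range(d)
#' @export
mixed_distance <- function(x, metric = c("gower", "euclidean"),
                           range_mode = c("observed", "theoretical")) {
  metric <- match.arg(metric)
  range_mode <- match.arg(range_mode)
  m <- if (is.matrix(x)) x else if (inherits(x, "numeric_scores")) {
    score_matrix(x)
  } else {
    as.matrix(as.data.frame(x))
  }
  storage.mode(m) <- "double"
  n <- nrow(m)
  p <- ncol(m)
  if (n < 2) abort("need at least 2 specimens")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  if (metric == "gower") {
    if (range_mode == "observed") {
      rng <- apply(m, 2, function(v) {
        v <- v[!is.na(v)]
        if (length(v) == 0) 0 else max(v) - min(v)
      })
      if (any(rng == 0)) {
        warn(paste0("character(s) with zero observed range dropped from ",
                    "Gower computation: ",
                    paste(colnames(m)[rng == 0], collapse = ", ")))
      }
    } else {
      def <- character_definitions(x)
      idx <- match(colnames(m), def$code)
      if (anyNA(idx)) {
        abort("theoretical ranges require character definitions matching the columns")
      }
      rng <- as.numeric(def$max_state[idx] - def$min_state[idx])
    }
    use <- rng > 0
    m <- m[, use, drop = FALSE]
    rng <- rng[use]
  }

  D <- matrix(0, n, n, dimnames = list(labels, labels))
  obs <- !is.na(m)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      shared <- obs[i, ] & obs[j, ]
      ns <- sum(shared)
      if (ns == 0) {
        abort(sprintf("specimens '%s' and '%s' share no scored characters",
                      labels[i], labels[j]))
      }
      diffs <- abs(m[i, shared] - m[j, shared])
      D[i, j] <- D[j, i] <- if (metric == "gower") {
        mean(diffs / rng[shared])
      } else {
        sqrt(sum(diffs^2) * p / ns)
      }
    }
  }
  stats::as.dist(D)
}
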