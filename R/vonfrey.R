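# Up-down (Dixon) estimation of the 50% paw-withdrawal threshold from
# von Frey monofilament response sequences, with a probit maximum-
# likelihood oracle that generates the pattern coefficient table.

#' Standard 10-filament von Frey set
#'
#' Forces in grams spanning 0.4-15 g; testing starts at the 2 g filament.
#'
#' @return numeric vector of 10 filament forces, g.
#' @export
vf_filament_set <- function() c(0.4, 0.6, 1, 1.4, 2, 4, 6, 8, 10, 15)

VF_START_G <- 2

.vf_delta <- function(filaments) mean(diff(log10(filaments)))

.vf_pattern <- function(response) paste(ifelse(response, "+", "-"),
                                        collapse = "")

# Walk the idealized uniform log-spaced lattice implied by a response
# pattern, anchored so that the final presented position is 0 (in units of
# the lattice spacing).  Position j+1 is one step lighter after a positive
# response and one step heavier after a negative one.
.vf_positions <- function(response) {
  n <- length(response)
  pos <- numeric(n)
  for (j in seq_len(n - 1))
    pos[j + 1] <- pos[j] + if (response[j]) -1 else 1
  pos - pos[n]
}

#' Probit maximum-likelihood oracle for an up-down response pattern
#'
#' Fits a probit psychometric function
#' \eqn{P(+\,|\,x) = \Phi((x - \mu)/\sigma)} to the responses of one
#' up-down sequence on the idealized uniform log-force lattice (spacing
#' `delta`, slope `sigma`, anchored at the final presented filament) and
#' returns the maximum-likelihood 50% point.  This brute-force estimator
#' defines the pattern coefficients `k` used by [vonfrey_50pwt()]:
#' `k = (mu - x_final) / delta` depends only on the response pattern when
#' `sigma = delta`.
#'
#' @param response logical vector (TRUE = positive/withdrawal response) or
#'   a pattern string such as `"-+-+"`.
#' @param final_g force of the final presented filament, g.
#' @param delta lattice spacing in log10 g units.
#' @param sigma psychometric slope in log10 g units; defaults to `delta`
#'   (the classical up-down assumption).
#' @return list with `mu` (log10 g), `threshold_g` (`10^mu`) and `k`.
#' @export
vonfrey_probit_mle <- function(response, final_g = VF_START_G,
                               delta = .vf_delta(vf_filament_set()),
                               sigma = delta) {
  if (is.character(response))
    response <- strsplit(response, "")[[1]] == "+"
  stopifnot(length(response) >= 1, is.logical(response))
  if (all(response) || all(!response))
    stop("probit MLE undefined for an all-same response pattern (boundary rule applies)")
  x_f <- log10(final_g)
  x <- x_f + .vf_positions(response) * delta
  nll <- function(mu) {
    pr <- pnorm((x - mu) / sigma)
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    -sum(ifelse(response, log(pr), log(1 - pr)))
  }
  o <- optimize(nll, interval = c(x_f - 8 * delta, x_f + 8 * delta),
                tol = 1e-9)
  mu <- o$minimum
  list(mu = mu, threshold_g = 10^mu, k = (mu - x_f) / delta)
}

#' Enumerate valid up-down response patterns
#'
#' Walks every response sequence the up-down rule can generate on a
#' filament set: starting at 2 g, a positive response moves to the next
#' lighter filament and a negative one to the next heavier; testing stops
#' after four responses beyond the first change, or when the walk would
#' leave the set.  All-same patterns (handled by the boundary rules) are
#' excluded.
#'
#' @param filaments the filament set, g.
#' @return character vector of `+`/`-` pattern strings.
#' @export
enumerate_updown_patterns <- function(filaments = vf_filament_set()) {
  nf <- length(filaments)
  start <- match(VF_START_G, filaments)
  out <- character(0)
  recurse <- function(idx, resp) {
    for (r in c(TRUE, FALSE)) {
      seq_r <- c(resp, r)
      changed <- any(seq_r != seq_r[1])
      post <- if (changed) length(seq_r) - match(TRUE, seq_r != seq_r[1]) + 1
              else 0
      nxt <- idx + if (r) -1L else 1L
      # stop after the change response plus four more, or at the set edge
      done <- (changed && post >= 5) || nxt < 1 || nxt > nf
      if (done) {
        if (changed) out[[length(out) + 1]] <<- .vf_pattern(seq_r)
      } else {
        recurse(nxt, seq_r)
      }
    }
  }
  recurse(start, logical(0))
  sort(unique(out))
}

#' Build the up-down pattern coefficient table
#'
#' Computes the Dixon-style pattern coefficient `k` for every valid
#' up-down response pattern using the probit maximum-likelihood oracle
#' ([vonfrey_probit_mle()]).  The packaged copy of this table lives at
#' `inst/extdata/vonfrey_k_table.csv`; this generator reproduces it.
#'
#' @param patterns pattern strings; defaults to the full enumeration.
#' @return tibble with columns `pattern` and `k`.
#' @export
build_vonfrey_k_table <- function(patterns = enumerate_updown_patterns()) {
  k <- vapply(patterns, function(pt) vonfrey_probit_mle(pt)$k, numeric(1))
  tibble::tibble(pattern = patterns, k = unname(k))
}

.vf_cache <- new.env(parent = emptyenv())

.vf_k_lookup <- function(pattern) {
  if (is.null(.vf_cache$table)) {
    path <- system.file("extdata", "vonfrey_k_table.csv",
                        package = "axotrace")
    .vf_cache$table <- if (nzchar(path))
      utils::read.csv(path, stringsAsFactors = FALSE)
    else data.frame(pattern = character(0), k = numeric(0))
  }
  tab <- .vf_cache$table
  i <- match(pattern, tab$pattern)
  if (!is.na(i)) return(tab$k[i])
  vonfrey_probit_mle(pattern)$k  # fall back to the oracle
}

.vf_validate_sequence <- function(filament, response, filaments) {
  n <- length(filament)
  if (filament[1] != VF_START_G)
    stop("up-down sequence must start at the ", VF_START_G, " g filament")
  idx <- match(filament, filaments)
  if (any(is.na(idx)))
    stop("filament force not in the filament set: ",
         paste(filament[is.na(idx)], collapse = ", "))
  for (j in seq_len(n - 1)) {
    expected <- idx[j] + if (response[j]) -1L else 1L
    if (idx[j + 1] != expected)
      stop(sprintf(
        "up-down rule violated at presentation %d: a %s response at %g g must be followed by %s g",
        j + 1, if (response[j]) "positive" else "negative", filament[j],
        if (expected >= 1 && expected <= length(filaments))
          format(filaments[expected]) else "no filament (end of set)"))
  }
  idx
}

#' 50% paw-withdrawal threshold from an up-down response sequence
#'
#' Implements the up-down (Dixon) estimator on the 10-filament 0.4-15 g
#' set: continuous positive responses down to the weakest filament are
#' assigned 0.4 g and continuous negative responses up to the strongest
#' 15 g; any other valid sequence is scored as
#' \deqn{PWT = 10^{x_f + k\,\delta}}
#' where `x_f` is the log10 force of the final filament, `delta` the mean
#' log10 spacing of the set and `k` the pattern coefficient from the
#' packaged probit-MLE table.  The result is clamped to the 0.4-15 g range
#' of the set.
#'
#' @param sequence data frame with columns `filament_g` and `response`
#'   (logical, or `"+"`/`"-"` characters), one row per presentation in
#'   order.
#' @param filaments the filament set, g.
#' @return 50% paw-withdrawal threshold, g.
#' @examples
#' seqs <- data.frame(filament_g = c(2, 4, 2, 4, 6),
#'                    response = c("-", "+", "-", "-", "+"))
#' vonfrey_50pwt(seqs)
#' @export
vonfrey_50pwt <- function(sequence, filaments = vf_filament_set()) {
  stopifnot(is.data.frame(sequence),
            all(c("filament_g", "response") %in% names(sequence)))
  filament <- sequence$filament_g
  response <- sequence$response
  if (is.character(response) || is.factor(response))
    response <- as.character(response) == "+"
  stopifnot(is.logical(response), length(filament) == length(response),
            length(filament) >= 1)
  .vf_validate_sequence(filament, response, filaments)
  n <- length(response)
  if (all(response)) {
    if (filament[n] != min(filaments))
      stop("all-positive sequence must continue to the weakest filament")
    return(min(filaments))
  }
  if (all(!response)) {
    if (filament[n] != max(filaments))
      stop("all-negative sequence must continue to the strongest filament")
    return(max(filaments))
  }
  delta <- .vf_delta(filaments)
  k <- .vf_k_lookup(.vf_pattern(response))
  pwt <- 10^(log10(filament[n]) + k * delta)
  min(max(pwt, min(filaments)), max(filaments))
}
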