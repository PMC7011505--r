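# End-to-end benchmark: build the synthetic dataset, index the canvases
# at the slot centres, search each centred icon query, and score hits by
# icon class -- optionally after degrading the database canvases with
# salt-and-pepper noise. Queries are always searched clean.

#' Run the retrieval benchmark for one dataset seed
#'
#' Indexes the canvases of one generated dataset at their 81 slot
#' centres (window `S = spec$frame`), describes the 9 clean queries at
#' their frame centres, and scores rank-1 accuracy and the top-k hit
#' fraction. With `noise > 0` every canvas is degraded with
#' salt-and-pepper noise before indexing; the noise mask seed is derived
#' deterministically from the dataset seed, the canvas number and the
#' noise level.
#'
#' @param dataset Output of [build_dataset()]; built from `spec` if
#'   omitted.
#' @param spec A [dataset_spec()]; the seed inside it identifies the
#'   replicate.
#' @param noise Salt-and-pepper density applied to database canvases
#'   (0 = clean).
#' @param k Ranking depth (default 5).
#' @return List: `score` (see [score_retrieval()]), `index`, `results`,
#'   `noise`, `seed`.
#' @export
run_replicate <- function(dataset = NULL, spec = dataset_spec(),
                          noise = 0, k = 5L) {
  if (is.null(dataset)) dataset <- build_dataset(spec)
  spec <- dataset$spec
  S <- spec$frame
  canvases <- dataset$canvases
  if (noise > 0)
    canvases <- lapply(seq_along(canvases), function(i)
      add_salt_pepper(canvases[[i]], noise,
                      seed = spec$seed * 1000L + i * 101L +
                             as.integer(round(noise * 100))))
  centers <- slot_centers(spec$canvas, spec$slots)
  idx <- db_index(canvases, pois = rep(list(centers), length(canvases)),
                  S = S)
  qpoi <- spec$frame %/% 2
  results <- lapply(dataset$queries, function(q)
    db_search(describe_poi(q, qpoi, qpoi, S = S), idx, k = k))
  score <- score_retrieval(results, dataset$truth, spec, k = k)
  list(score = score, index = idx, results = results,
       noise = noise, seed = spec$seed)
}

#' Benchmark report over seeds and noise levels
#'
#' Replicates the retrieval experiment for each seed and noise level and
#' tabulates hit counts in the style of a retrieval accuracy table
#' (x/9 rank-1 hits, y/45 top-5 hits per replicate, plus means).
#'
#' @param seeds Integer vector of dataset seeds.
#' @param noise_levels Salt-and-pepper densities to test.
#' @param k Ranking depth.
#' @param spec_fn Function mapping a seed to a [dataset_spec()]; the
#'   default uses the reference protocol defaults.
#' @param quiet Suppress progress output?
#' @return Data frame with one row per (seed, noise): `seed`, `noise`,
#'   `top1_hits`, `n_queries`, `topk_hits`, `n_topk`, `top1`, `topk`.
#' @examples
#' \donttest{
#' report <- run_benchmark(seeds = 1, noise_levels = 0)
#' }
#' @export
run_benchmark <- function(seeds = 1:3, noise_levels = c(0, 0.1, 0.2, 0.3),
                          k = 5L, spec_fn = function(s) dataset_spec(seed = s),
                          quiet = FALSE) {
  rows <- list()
  for (s in seeds) {
    spec <- spec_fn(s)
    dataset <- build_dataset(spec)
    for (nz in noise_levels) {
      rep <- run_replicate(dataset, noise = nz, k = k)
      sc <- rep$score
      nq <- spec$n_icons
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, noise = nz,
        top1_hits = sc$top1_hits, n_queries = nq,
        topk_hits = sc$topk_hits, n_topk = nq * k,
        top1 = sc$top1, topk = sc$topk)
      if (!quiet)
        message(sprintf(
          "seed %d noise %.2f: top-1 %d/%d (%.1f%%), top-%d %d/%d (%.1f%%)",
          s, nz, sc$top1_hits, nq, 100 * sc$top1, k,
          sc$topk_hits, nq * k, 100 * sc$topk))
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  report
}
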