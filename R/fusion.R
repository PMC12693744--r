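#' Majority-voting policy
#'
#' One inspection cycle samples the same nest `n_frames` times (default 3,
#' at 10 s intervals, so samples are separated by more than the duration of
#' typical transient interference and are approximately independent) and
#' declares a state when at least `threshold` frames agree (default 2).
#'
#' @param n_frames number of samples N per cycle, >= 1.
#' @param threshold vote threshold T, `1 <= T <= N`.
#' @param sample_interval seconds between samples (metadata; default 10).
#' @param match_radius pixel radius for matching the same egg across frames
#'   (eggs may roll slightly between samples); default 40 px at 1920x1080.
#' @return An object of class `"voting_policy"`.
#' @export
voting_policy <- function(n_frames = 3L, threshold = 2L,
                          sample_interval = 10, match_radius = 40) {
  n_frames <- as.integer(n_frames); threshold <- as.integer(threshold)
  if (is.na(n_frames) || n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  if (is.na(threshold) || threshold < 1 || threshold > n_frames) {
    stop("threshold must satisfy 1 <= T <= N", call. = FALSE)
  }
  structure(list(n_frames = n_frames, threshold = threshold,
                 sample_interval = sample_interval,
                 match_radius = match_radius),
            class = "voting_policy")
}

#' Binomial reliability of the voting system
#'
#' For per-frame detection probability `p_detect` and independent frames,
#' the probability that at least T of N frames detect a truly present egg:
#' the exact binomial tail sum
#' \deqn{P_{system} = \sum_{k=T}^{N} \binom{N}{k} P_d^k (1-P_d)^{N-k}.}
#' At `p_detect = 0.8`, N = 3, T = 2 this is 0.896: system reliability well
#' above the single-frame rate.
#'
#' @param p_detect per-frame detection probability in \[0, 1\] (vectorised).
#' @param policy a [voting_policy()].
#' @return probability in \[0, 1\].
#' @examples
#' system_reliability(0.8, voting_policy(3, 2))  # 0.896
#' @export
system_reliability <- function(p_detect, policy = voting_policy()) {
  if (any(p_detect < 0 | p_detect > 1)) {
    stop("p_detect must lie in [0, 1]", call. = FALSE)
  }
  n <- policy$n_frames
  k <- policy$threshold:n
  vapply(p_detect, function(p) {
    sum(choose(n, k) * p^k * (1 - p)^(n - k))
  }, numeric(1))
}

check_cycle_frames <- function(frames, policy) {
  if (length(frames) != policy$n_frames) {
    stop(sprintf("expected %d frames per cycle, got %d",
                 policy$n_frames, length(frames)), call. = FALSE)
  }
  for (fr in frames) {
    if (!inherits(fr, "frame_result")) {
      stop("frames must be frame_result objects", call. = FALSE)
    }
  }
  invisible(frames)
}

#' Fused nest-level egg presence
#'
#' A nest is declared occupied when at least T of the N frames contain at
#' least one detection.
#'
#' @param frames list of exactly N [frame_result()] objects.
#' @param policy a [voting_policy()].
#' @return logical flag.
#' @export
fuse_presence <- function(frames, policy = voting_policy()) {
  check_cycle_frames(frames, policy)
  n_positive <- sum(vapply(frames, function(fr) length(fr$detections) > 0,
                           logical(1)))
  n_positive >= policy$threshold
}

#' Fused per-egg count across frames
#'
#' Generalises the nest-level vote to per-egg granularity: detections from
#' all frames are clustered by greedy nearest-center matching (processed in
#' descending confidence, ties broken by lower frame index), a detection
#' joining the nearest cluster within `match_radius` that does not already
#' contain a detection from its frame. Clusters supported by at least T
#' distinct frames each contribute one egg; single-frame spurious
#' detections are filtered out.
#'
#' @inheritParams fuse_presence
#' @return An object of class `"fusion_decision"`: list with `egg_present`,
#'   `fused_count`, and `per_egg_support` (one entry per retained cluster,
#'   with the cluster center and its supporting frame indices).
#' @export
fuse_count <- function(frames, policy = voting_policy()) {
  check_cycle_frames(frames, policy)
  rows <- list()
  for (fr in frames) {
    for (d in fr$detections) {
      ctr <- box_center(d$box)
      rows[[length(rows) + 1L]] <- list(frame = fr$frame_index,
                                        conf = d$confidence,
                                        x = ctr[["x"]], y = ctr[["y"]])
    }
  }
  clusters <- list()  # each: list(x, y, frames, n)
  if (length(rows) > 0) {
    conf <- vapply(rows, `[[`, numeric(1), "conf")
    fidx <- vapply(rows, `[[`, numeric(1), "frame")
    ord <- order(-conf, fidx)
    for (i in ord) {
      r <- rows[[i]]
      best <- 0L; best_d <- Inf
      for (ci in seq_along(clusters)) {
        cl <- clusters[[ci]]
        if (r$frame %in% cl$frames) next
        d2 <- sqrt((cl$x - r$x)^2 + (cl$y - r$y)^2)
        if (d2 <= policy$match_radius && d2 < best_d) {
          best <- ci; best_d <- d2
        }
      }
      if (best == 0L) {
        clusters[[length(clusters) + 1L]] <-
          list(x = r$x, y = r$y, frames = r$frame, n = 1L)
      } else {
        cl <- clusters[[best]]
        # running mean keeps the cluster center stable and deterministic
        cl$x <- (cl$x * cl$n + r$x) / (cl$n + 1L)
        cl$y <- (cl$y * cl$n + r$y) / (cl$n + 1L)
        cl$frames <- c(cl$frames, r$frame)
        cl$n <- cl$n + 1L
        clusters[[best]] <- cl
      }
    }
  }
  keep <- Filter(function(cl) length(unique(cl$frames)) >= policy$threshold,
                 clusters)
  support <- lapply(keep, function(cl) {
    list(center = c(x = cl$x, y = cl$y), frames = sort(unique(cl$frames)))
  })
  structure(list(egg_present = length(keep) >= 1L,
                 fused_count = length(keep),
                 per_egg_support = support),
            class = "fusion_decision")
}

#' @export
print.fusion_decision <- function(x, ...) {
  cat(sprintf("<fusion: present=%s, count=%d>\n",
              x$egg_present, x$fused_count))
  invisible(x)
}

#' Monte-Carlo check of the voting reliability model
#'
#' Draws per-frame Bernoulli(`p_detect`) detection successes for an
#' occupied nest over many cycles, applies the T-of-N vote, and returns the
#' observed miss rate (fraction of cycles voting "absent"). Converges to
#' `1 - system_reliability(p_detect, policy)`.
#'
#' @inheritParams system_reliability
#' @param n_cycles number of simulated cycles, >= 1.
#' @param seed RNG seed (the simulation is deterministic given the seed).
#' @return observed miss rate in \[0, 1\].
#' @export
simulate_cycles <- function(p_detect, policy = voting_policy(),
                            n_cycles = 10000L, seed = 1L) {
  stopifnot(n_cycles >= 1)
  if (p_detect < 0 || p_detect > 1) {
    stop("p_detect must lie in [0, 1]", call. = FALSE)
  }
  local_seed(seed, {
    hits <- rbinom(n_cycles, policy$n_frames, p_detect)
    mean(hits < policy$threshold)
  })
}
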