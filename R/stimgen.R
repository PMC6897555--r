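# Texture stimulus generation: 6x6 micro-feature tiles paired into six
# binary feature pairs, 30x30 tile grids (900 tiles, 180x180 px native),
# category schemes with k covariant pairs, trial schedules and rating pairs.

#' Build the twelve micro-feature tiles
#'
#' Each tile is a 6x6 binary pattern with exactly 18 black (1) and 18 white
#' (0) pixels. The twelve distinct patterns are paired arbitrarily (but
#' deterministically in `seed`) into six mutually exclusive binary feature
#' pairs: pair `p` has a polarity-0 and a polarity-1 tile, and
#' `tile_id = 2 * pair_id + polarity`.
#'
#' @param seed Non-negative integer seed.
#' @return An object of class `"tile_set"`: a list of 12 tiles, each with
#'   `tile_id` (0-11), `pair_id` (0-5), `polarity` (0/1) and `pattern`
#'   (6x6 integer matrix).
#' @export
#' @examples
#' tiles <- build_tiles(1)
#' sum(tiles[[1]]$pattern)  # always 18
build_tiles <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  with_seed(derive_seed(seed, "tiles"), {
    patterns <- list()
    keys <- character(0)
    while (length(patterns) < 12) {
      cells <- sample(c(rep(1L, 18), rep(0L, 18)))
      key <- paste(cells, collapse = "")
      if (!key %in% keys) {           # distinctness; collisions are ~impossible
        keys <- c(keys, key)
        patterns[[length(patterns) + 1]] <- matrix(cells, 6, 6)
      }
    }
    # arbitrary pairing: a random permutation of the 12 patterns,
    # consecutive patterns forming a pair
    ord <- sample(12L)
    tiles <- vector("list", 12)
    for (p in 0:5) {
      for (pol in 0:1) {
        id <- 2L * p + pol
        tiles[[id + 1]] <- list(
          tile_id = id, pair_id = p, polarity = pol,
          pattern = patterns[[ord[id + 1]]]
        )
      }
    }
    structure(tiles, class = "tile_set", seed = seed)
  })
}

#' Define a category scheme with k covariant feature pairs
#'
#' Picks one arbitrary combination of `k` of the six feature pairs to covary
#' with category membership, and for each covariant pair the polarity that
#' signals category K (the opposite polarity signals L). Non-covariant pairs
#' vary randomly, independent of category.
#'
#' @param k Number of covariant pairs, 0 to 6 (6/6 easiest, 3/6 the hardest
#'   level used in training; 0 is a pure-noise control).
#' @param seed Non-negative integer seed.
#' @return A `"feature_scheme"`: list with `k`, `covariant_pairs`
#'   (sorted pair ids), `polarity_map` (named integer vector over covariant
#'   pairs giving the K polarity) and `seed`.
#' @export
make_scheme <- function(k, seed) {
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 0 || k > 6) {
    stop("invalid difficulty: k must be an integer in 0..6")
  }
  k <- as.integer(k)
  with_seed(derive_seed(seed, "scheme", k), {
    pairs <- if (k > 0) sort(sample(0:5, k)) else integer(0)
    pol <- if (k > 0) sample(0:1, k, replace = TRUE) else integer(0)
    names(pol) <- as.character(pairs)
    structure(list(k = k, covariant_pairs = pairs, polarity_map = pol,
                   seed = seed),
              class = "feature_scheme")
  })
}

#' Generate one texture stimulus
#'
#' The polarity vector has its covariant entries fixed by the category
#' (through the scheme's polarity map) and its non-covariant entries drawn
#' as independent fair coin flips. The 30x30 grid holds the six selected
#' tiles in a uniformly random arrangement with each tile occurring exactly
#' 150 times (900 / 6), so all six features are equally represented in every
#' stimulus.
#'
#' @param scheme A `"feature_scheme"`.
#' @param category `"K"` or `"L"`.
#' @param seed Non-negative integer seed.
#' @param stimulus_id Optional id string; defaults to a seed-derived label.
#' @return A `"texture_stimulus"`: list with `stimulus_id`, `category`,
#'   `polarity_vector` (length 6, pairs 0-5), `grid` (30x30 matrix of tile
#'   ids) and `rendered_size`.
#' @export
make_texture <- function(scheme, category, seed, stimulus_id = NULL) {
  stopifnot(inherits(scheme, "feature_scheme"))
  category <- match.arg(category, c("K", "L"))
  with_seed(derive_seed(seed, "texture", category), {
    pol <- integer(6)
    free <- setdiff(0:5, scheme$covariant_pairs)
    for (p in scheme$covariant_pairs) {
      kside <- scheme$polarity_map[[as.character(p)]]
      pol[p + 1] <- if (category == "K") kside else 1L - kside
    }
    pol[free + 1] <- sample(0:1, length(free), replace = TRUE)
    tile_ids <- 2L * 0:5 + pol
    grid <- matrix(sample(rep(tile_ids, each = 150L)), 30, 30)
    structure(list(
      stimulus_id = stimulus_id %||% sprintf("s%010d", derive_seed(seed, category)),
      category = category, polarity_vector = pol, grid = grid,
      rendered_size = 275L, seed = seed
    ), class = "texture_stimulus")
  })
}

#' Generate a full stimulus set
#'
#' @param scheme A `"feature_scheme"`.
#' @param n Total number of stimuli (even; default 180 giving 90 per
#'   category).
#' @param seed Non-negative integer seed; each stimulus gets its own derived
#'   sub-seed.
#' @return A `"stimulus_set"`: list with `scheme`, `stimuli` (list of
#'   textures) and `n_per_category`.
#' @export
make_set <- function(scheme, n = 180, seed = 1) {
  stopifnot(inherits(scheme, "feature_scheme"))
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n %% 2 != 0) {
    stop("invalid set size: n must be an even count >= 2")
  }
  n <- as.integer(n)
  cats <- rep(c("K", "L"), each = n / 2)
  stimuli <- vector("list", n)
  for (i in seq_len(n)) {
    stimuli[[i]] <- make_texture(scheme, cats[i], derive_seed(seed, "stim", i),
                                 stimulus_id = sprintf("%s%03d", cats[i],
                                                       ((i - 1) %% (n / 2)) + 1))
  }
  structure(list(scheme = scheme, stimuli = stimuli, n_per_category = n %/% 2L),
            class = "stimulus_set", seed = seed)
}

set_ids <- function(set) vapply(set$stimuli, `[[`, "", "stimulus_id")
set_categories <- function(set) vapply(set$stimuli, `[[`, "", "category")

#' Build a training trial schedule
#'
#' Every stimulus is shown two or three times: `n_trials - 2 * n_stimuli`
#' stimuli (chosen at random) get a third presentation, and the full multiset
#' is uniformly shuffled. With the default 180 stimuli and 400 trials, 40
#' stimuli appear three times and 140 twice. Trials are grouped into blocks
#' of 100 for block-level summaries.
#'
#' @param set A `"stimulus_set"`.
#' @param n_trials Total trials (default 400); must lie in
#'   `[2 * n_stimuli, 3 * n_stimuli]`.
#' @param seed Non-negative integer seed.
#' @return A `"trial_schedule"`: list with `stimulus_id` (character vector of
#'   length `n_trials`), `category` (matched true categories), `block_size`.
#' @export
build_schedule <- function(set, n_trials = 400, seed = 1) {
  stopifnot(inherits(set, "stimulus_set"))
  ids <- set_ids(set)
  n <- length(ids)
  if (n_trials < 2 * n || n_trials > 3 * n) {
    stop("infeasible schedule: n_trials must be in [2*n_stimuli, 3*n_stimuli]")
  }
  n_trials <- as.integer(n_trials)
  with_seed(derive_seed(seed, "schedule", n_trials), {
    counts <- rep(2L, n)
    extra <- n_trials - 2L * n
    if (extra > 0) counts[sample(n, extra)] <- 3L
    order_ids <- sample(rep(ids, counts))
    cat_of <- stats::setNames(set_categories(set), ids)
    structure(list(stimulus_id = order_ids,
                   category = unname(cat_of[order_ids]),
                   block_size = 100L, n_trials = n_trials),
              class = "trial_schedule", seed = seed)
  })
}

#' Rasterize a texture and write it as a PNG
#'
#' The native raster is 180x180 px (30 tiles of 6x6); black tile pixels map
#' to intensity 0 and white to 1. When `final_size` differs from 180 the
#' raster is smoothly resampled (bilinear, via EBImage) to the requested
#' size, 275x275 by default. The analysis pipeline only ever consumes tile
#' grids, never resized pixels.
#'
#' @param texture A `"texture_stimulus"`.
#' @param tiles The `"tile_set"` used to build the stimuli.
#' @param path Output file path (.png).
#' @param final_size Output edge length in pixels (default 275; use 180 for
#'   the native raster).
#' @return Invisibly, the written raster matrix (grayscale in `[0, 1]`).
#' @export
render_png <- function(texture, tiles, path, final_size = 275) {
  stopifnot(inherits(texture, "texture_stimulus"), inherits(tiles, "tile_set"))
  raster <- render_raster(texture, tiles)
  if (final_size != 180L) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("resizing requires the EBImage package; use final_size = 180 for the native raster")
    }
    img <- EBImage::resize(EBImage::Image(raster), w = final_size,
                           h = final_size, filter = "bilinear")
    raster <- pmin(pmax(EBImage::imageData(img), 0), 1)
  }
  ok <- tryCatch({png::writePNG(raster, target = path); TRUE},
                 error = function(e) FALSE)
  if (!ok) stop("could not write PNG to ", path)
  invisible(raster)
}

#' Compose the native 180x180 grayscale raster of a texture
#'
#' @inheritParams render_png
#' @return A 180x180 numeric matrix in `[0, 1]` (0 = black).
#' @export
render_raster <- function(texture, tiles) {
  raster <- matrix(0, 180, 180)
  for (r in 1:30) {
    for (c in 1:30) {
      pat <- tiles[[texture$grid[r, c] + 1]]$pattern
      raster[(6 * r - 5):(6 * r), (6 * c - 5):(6 * c)] <- 1 - pat
    }
  }
  raster
}

#' Sample the forty dissimilarity-rating pairs
#'
#' Draws 20 within-category pairs (10 K-K and 10 L-L) and 20 between-category
#' pairs, with no pair repeated, and fixes a presentation order that is
#' reused identically in the pre- and post-training rating phases.
#'
#' @param set A `"stimulus_set"` with at least 10 stimuli per category.
#' @param seed Non-negative integer seed.
#' @return A data frame of class `"rating_pair_set"`, columns `pair_index`,
#'   `stim1`, `stim2`, `pair_type` (`"within"`/`"between"`), `subtype`
#'   (`"KK"`, `"LL"`, `"KL"`).
#' @export
sample_rating_pairs <- function(set, seed = 1) {
  stopifnot(inherits(set, "stimulus_set"))
  ids <- set_ids(set)
  cats <- set_categories(set)
  ks <- ids[cats == "K"]; ls <- ids[cats == "L"]
  if (length(ks) < 10 || length(ls) < 10) {
    stop("invalid set: need at least 10 stimuli per category")
  }
  with_seed(derive_seed(seed, "pairs"), {
    draw_pairs <- function(a, b, n, subtype) {
      seen <- character(0)
      out <- vector("list", n)
      i <- 1
      while (i <= n) {
        s1 <- sample(a, 1); s2 <- sample(b, 1)
        if (s1 == s2) next
        key <- paste(sort(c(s1, s2)), collapse = "|")
        if (key %in% seen) next
        seen <- c(seen, key)
        out[[i]] <- data.frame(stim1 = s1, stim2 = s2, subtype = subtype,
                               stringsAsFactors = FALSE)
        i <- i + 1
      }
      do.call(rbind, out)
    }
    tab <- rbind(draw_pairs(ks, ks, 10, "KK"),
                 draw_pairs(ls, ls, 10, "LL"),
                 draw_pairs(ks, ls, 20, "KL"))
    tab$pair_type <- ifelse(tab$subtype == "KL", "between", "within")
    tab <- tab[sample(nrow(tab)), c("stim1", "stim2", "pair_type", "subtype")]
    tab$pair_index <- seq_len(nrow(tab))
    rownames(tab) <- NULL
    structure(tab[, c("pair_index", "stim1", "stim2", "pair_type", "subtype")],
              class = c("rating_pair_set", "data.frame"), seed = seed)
  })
}

#' Classify a stimulus from its covariant polarities
#'
#' The ideal-observer rule: read only the covariant pairs and return K when
#' they match the scheme's K polarity map (which they always do for
#' generated stimuli, making any k >= 1 set perfectly decodable). With
#' k = 0 the rule is undefined and `NA` is returned.
#'
#' @param texture A `"texture_stimulus"`.
#' @param scheme The `"feature_scheme"` that generated it.
#' @return `"K"`, `"L"`, or `NA` for k = 0.
#' @export
decode_category <- function(texture, scheme) {
  if (scheme$k == 0) return(NA_character_)
  pv <- texture$polarity_vector[scheme$covariant_pairs + 1]
  kside <- unname(scheme$polarity_map[as.character(scheme$covariant_pairs)])
  if (all(pv == kside)) "K" else if (all(pv == 1L - kside)) "L" else NA_character_
}

#' Write a stimulus-set manifest
#'
#' @param set A `"stimulus_set"`.
#' @param path Output TSV path.
#' @return Invisibly, the manifest data frame (stimulus_id, category,
#'   polarity vector as a 6-character string, per-stimulus seed).
#' @export
write_manifest <- function(set, path) {
  man <- data.frame(
    stimulus_id = set_ids(set),
    category = set_categories(set),
    polarity = vapply(set$stimuli,
                      function(s) paste(s$polarity_vector, collapse = ""), ""),
    seed = vapply(set$stimuli, function(s) s$seed, numeric(1))
  )
  utils::write.table(man, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(man)
}
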