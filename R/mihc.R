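#' Read a per-cell mIHC intensity table
#'
#' CSV with columns `cell_id`, `region`, then one column per fluorescence
#' channel (mean intensity, non-negative).
#'
#' @param path CSV file.
#' @return A data.frame of class `cell_intensity_table`.
#' @export
read_intensity_table <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  cell_intensity_table(dt)
}

#' Construct a per-cell mIHC intensity table
#'
#' @param df data.frame with columns `cell_id`, `region` and one numeric
#'   column per channel.
#' @return The validated data.frame, classed `cell_intensity_table`.
#' @export
cell_intensity_table <- function(df) {
  assert_that(all(c("cell_id", "region") %in% names(df)),
              "intensity table needs cell_id and region columns")
  channels <- setdiff(names(df), c("cell_id", "region"))
  assert_that(length(channels) >= 1, "no channel columns found")
  for (ch in channels) {
    assert_that(is.numeric(df[[ch]]) && all(is.finite(df[[ch]])) &&
                  all(df[[ch]] >= 0),
                paste0("channel ", ch, " must be finite and >= 0 for every cell"))
  }
  assert_that(!anyDuplicated(df$cell_id), "duplicate cell ids")
  attr(df, "channels") <- channels
  class(df) <- c("cell_intensity_table", "data.frame")
  df
}

#' Construct a quadrant gating configuration
#'
#' Thresholds are required user inputs, set per slide from the staining of
#' each channel; no automatic thresholding is attempted. Positivity is strict
#' (`intensity > threshold`); a cell exactly at a threshold is negative.
#'
#' @param thresholds named numeric vector: channel name -> positivity
#'   threshold (> 0).
#' @param roles named character vector with entries `A`, `B`, `C` assigning
#'   channels to the baseline protein (A) and the two quadrant axes (B, C).
#' @return A list of class `gating_config`.
#' @export
gating_config <- function(thresholds, roles) {
  assert_that(all(c("A", "B", "C") %in% names(roles)),
              "roles must assign channels to A, B and C")
  roles <- roles[c("A", "B", "C")]
  missing <- setdiff(unname(roles), names(thresholds))
  assert_that(length(missing) == 0,
              paste0("no threshold for role channel(s): ",
                     paste(missing, collapse = ", ")))
  assert_that(all(thresholds > 0), "thresholds must be > 0")
  structure(list(thresholds = thresholds, roles = roles),
            class = "gating_config")
}

#' Read a gating configuration from YAML
#'
#' Expected layout:
#' ```yaml
#' thresholds: {DAPI_AREG: 12.5, EGFR: 8.0, ERBB2: 9.0}
#' roles: {A: DAPI_AREG, B: EGFR, C: ERBB2}
#' ```
#'
#' @param path YAML file.
#' @return A [gating_config()].
#' @export
read_gating_config <- function(path) {
  y <- yaml::read_yaml(path)
  gating_config(unlist(y$thresholds), unlist(y$roles))
}

#' Quadrant-gate positive cells
#'
#' Classifies each cell by channel positivity. Protein A-positive cells are
#' selected as the baseline population; among them the B/C intensity plane is
#' divided into four quadrants by the B and C thresholds, the upper-right
#' quadrant (`B+C+`) corresponding to triple-positive (`A+B+C+`) cells. A-
#' cells carry no quadrant.
#'
#' @param tbl a [cell_intensity_table()].
#' @param cfg a [gating_config()]; all three role channels must be present in
#'   the table.
#' @return A data.frame of class `gated_cells`: `cell_id`, `region`,
#'   `A_pos`, `B_pos`, `C_pos` (logical), `quadrant` (one of `"B+C+"`,
#'   `"B+C-"`, `"B-C+"`, `"B-C-"` among A+ cells, `NA` otherwise),
#'   `triple_positive`.
#' @export
gate_positive_cells <- function(tbl, cfg) {
  stopifnot(inherits(tbl, "cell_intensity_table"), inherits(cfg, "gating_config"))
  channels <- attr(tbl, "channels")
  missing <- setdiff(unname(cfg$roles), channels)
  assert_that(length(missing) == 0,
              paste0("missing channel(s) in intensity table: ",
                     paste(missing, collapse = ", ")))
  pos <- lapply(c(A = "A", B = "B", C = "C"), function(role) {
    ch <- cfg$roles[[role]]
    tbl[[ch]] > cfg$thresholds[[ch]]
  })
  quadrant <- ifelse(
    pos$A,
    paste0(ifelse(pos$B, "B+", "B-"), ifelse(pos$C, "C+", "C-")),
    NA_character_)
  out <- data.frame(
    cell_id = tbl$cell_id,
    region = tbl$region,
    A_pos = pos$A, B_pos = pos$B, C_pos = pos$C,
    quadrant = quadrant,
    triple_positive = pos$A & pos$B & pos$C,
    stringsAsFactors = FALSE)
  class(out) <- c("gated_cells", "data.frame")
  out
}

#' Triple-positive cell fractions
#'
#' The proportion of triple-positive (`A+B+C+`) cells within the total cell
#' population, per region or overall. The denominator is all cells of the
#' region, not only A+ cells.
#'
#' @param gated a `gated_cells` data.frame from [gate_positive_cells()].
#' @param by_region summarize per region (default) or overall.
#' @return A data.frame: `region` (or `"ALL"`), `n_total`, `n_triple`,
#'   `fraction`.
#' @export
triple_positive_fraction <- function(gated, by_region = TRUE) {
  stopifnot(inherits(gated, "gated_cells"))
  assert_that(nrow(gated) > 0, "no gated cells")
  if (!by_region) {
    return(data.frame(region = "ALL",
                      n_total = nrow(gated),
                      n_triple = sum(gated$triple_positive),
                      fraction = mean(gated$triple_positive),
                      stringsAsFactors = FALSE))
  }
  regions <- unique(gated$region)
  do.call(rbind, lapply(regions, function(r) {
    g <- gated[gated$region == r, , drop = FALSE]
    data.frame(region = r, n_total = nrow(g),
               n_triple = sum(g$triple_positive),
               fraction = mean(g$triple_positive),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate a synthetic mIHC intensity table
#'
#' Generates per-cell channel intensities with known positivity structure for
#' testing the gating workflow: per region, each cell's positivity triplet is
#' drawn from the requested triple-positive fraction (with the remaining
#' probability spread over the other combinations), and intensities are drawn
#' log-normally above or below the channel threshold accordingly. All
#' thresholds are 1.0. This is synthetic data, not an emulation of any
#' scanner's output distribution.
#'
#' @param n_cells_per_region cells per region.
#' @param triple_fractions named numeric vector: region -> planted
#'   triple-positive fraction (within all cells of the region).
#' @param channels three channel names, in A, B, C role order.
#' @param seed RNG seed.
#' @return A list: `table` (a [cell_intensity_table()]), `config` (a
#'   [gating_config()]), `truth` (data.frame of planted per-region fractions).
#' @export
simulate_mihc_intensities <- function(n_cells_per_region = 500L,
                                      triple_fractions = c(N = 0.02, IM = 0.08,
                                                           PMC_P = 0.35, T = 0.20),
                                      channels = c("chanA", "chanB", "chanC"),
                                      seed = 1L) {
  assert_that(length(channels) == 3, "exactly three channels required")
  assert_that(all(triple_fractions >= 0 & triple_fractions <= 1),
              "triple_fractions must be in [0, 1]")
  with_seed(seed, {
    rows <- lapply(names(triple_fractions), function(region) {
      n <- n_cells_per_region
      f <- triple_fractions[[region]]
      # triple-positive with probability f; otherwise one of the seven other
      # positivity patterns, biased toward mostly-negative cells
      other <- expand.grid(A = c(TRUE, FALSE), B = c(TRUE, FALSE),
                           C = c(TRUE, FALSE))
      other <- other[!(other$A & other$B & other$C), ]
      w <- ifelse(rowSums(other) == 0, 4, 1)
      pick <- sample(nrow(other), n, replace = TRUE, prob = w / sum(w))
      is_triple <- stats::runif(n) < f
      pat <- other[pick, ]
      pat[is_triple, ] <- TRUE
      intensity <- function(positive) {
        ifelse(positive,
               exp(stats::rnorm(length(positive), mean = 1.0, sd = 0.5)),
               exp(stats::rnorm(length(positive), mean = -1.0, sd = 0.5)))
      }
      # clamp at the threshold so positivity is exactly the planted pattern
      clamp <- function(v, positive) {
        v[positive & v <= 1] <- 1 + 1e-6
        v[!positive & v > 1] <- 1
        v
      }
      a <- clamp(intensity(pat$A), pat$A)
      b <- clamp(intensity(pat$B), pat$B)
      cc <- clamp(intensity(pat$C), pat$C)
      df <- data.frame(region = region, A = a, B = b, C = cc,
                       stringsAsFactors = FALSE)
      names(df)[2:4] <- channels
      df
    })
    df <- do.call(rbind, rows)
    df <- cbind(cell_id = sprintf("mihc%05d", seq_len(nrow(df))), df)
    cfg <- gating_config(
      thresholds = stats::setNames(rep(1.0, 3), channels),
      roles = stats::setNames(channels, c("A", "B", "C")))
    truth <- data.frame(region = names(triple_fractions),
                        planted_fraction = unname(triple_fractions),
                        stringsAsFactors = FALSE)
    list(table = cell_intensity_table(df), config = cfg, truth = truth)
  })
}
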