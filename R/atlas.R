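#' Generate a synthetic cortical atlas
#'
#' Creates ROI metadata emulating a bilateral anatomical parcellation:
#' `n_roi` regions of interest split evenly between hemispheres, assigned to
#' the large anatomical lobes in fixed proportions (frontal 48, temporal 32,
#' limbic 28, occipital 20, parietal 20 out of 148, scaled to `n_roi` by
#' largest remainder within each hemisphere), with per-ROI mean cortical
#' thickness drawn from a clipped normal centred at 2.4 mm.
#'
#' @param n_roi even integer >= 4, total number of ROIs (both hemispheres).
#' @param seed integer seed; the result is a pure function of the arguments.
#' @return A `data.frame` with columns `roi_id` (0-based), `name`,
#'   `hemisphere` (`"left"`/`"right"`), `region` and `thickness_mm`.
#' @examples
#' atlas <- generate_atlas(148, seed = 1)
#' table(atlas$hemisphere)
#' @export
generate_atlas <- function(n_roi, seed = 1L) {
  if (length(n_roi) != 1L || n_roi < 4 || n_roi %% 2 != 0) {
    stop_invalid("invalid-argument: n_roi must be an even integer >= 4 (got %s)",
                 toString(n_roi))
  }
  n_roi <- as.integer(n_roi)
  props <- c(frontal = 48, temporal = 32, limbic = 28,
             occipital = 20, parietal = 20) / 148
  nh <- n_roi %/% 2L
  counts <- largest_remainder(props * nh, nh)
  region_h <- rep(names(props), counts)
  with_seed(seed, {
    hemisphere <- rep(c("left", "right"), each = nh)
    region <- c(region_h, region_h)
    thickness <- rnorm(n_roi, mean = 2.4, sd = 0.25)
    thickness <- pmin(pmax(thickness, 1.2), 4.0)
    data.frame(
      roi_id = 0:(n_roi - 1L),
      name = sprintf("%s_%s_%02d", substr(hemisphere, 1, 1), region,
                     stats::ave(seq_len(n_roi), hemisphere, region,
                                FUN = seq_along)),
      hemisphere = hemisphere,
      region = region,
      thickness_mm = thickness,
      stringsAsFactors = FALSE
    )
  })
}

# integer apportionment: floor, then distribute the remainder to the
# largest fractional parts (ties to the earlier category)
largest_remainder <- function(x, total) {
  base <- floor(x)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(x - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Write / read an atlas table as TSV
#'
#' @param atlas atlas `data.frame` from [generate_atlas()].
#' @param path file path.
#' @return `write_atlas_tsv` returns `path` invisibly; `read_atlas_tsv`
#'   returns the atlas `data.frame`.
#' @export
write_atlas_tsv <- function(atlas, path) {
  write.table(atlas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas_tsv
#' @export
read_atlas_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
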