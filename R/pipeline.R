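#' Measure one worm mask end to end
#'
#' Runs the full measurement chain on a clean, horizontally oriented mask:
#' skeletonize to the spine line, trace it with moving perpendicular
#' profiles, extend it to the worm's tips using the one-pixel outline,
#' measure the diameter at every spine point, and integrate the
#' truncated-cone series into length, volume and surface area.
#'
#' @param mask a validated, horizontal [worm_mask] (see [preprocess_mask]
#'   / [preprocess_image]).
#' @param step trace advance per iteration, px.
#' @param profile_half half-length of the tracing profile line, px.
#' @param probe_half half-length of the width probe, px; must exceed the
#'   worm's maximum radius.
#' @param prune_len skeleton spur-pruning length, px.
#' @param with_curvature include the curvature series in the result.
#' @param worm_id identifier carried into the morphometrics row.
#' @return list with `skeleton`, `edge`, `spine` (extended [spine_path]),
#'   `widths` (`width_profile`) and `morphometrics`.
#' @export
measure_worm <- function(mask, step = 4, profile_half = 20, probe_half = 30,
                         prune_len = 10L, with_curvature = FALSE,
                         worm_id = NA_character_) {
  skel <- skeletonize(mask, prune_len = prune_len)
  spine <- trace_full(skel, step = step, profile_half = profile_half,
                      scale = mask$scale)
  edge <- outline(mask)
  spine <- extend_ends(spine, edge)
  wp <- measure_widths(spine, edge, probe_half = probe_half)
  morpho <- total_morphometrics(wp, spine, worm_id = worm_id,
                                with_curvature = with_curvature)
  list(skeleton = skel, edge = edge, spine = spine, widths = wp,
       morphometrics = morpho)
}
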