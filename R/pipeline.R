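#' Run the full occupancy/TFBS comparison pipeline
#'
#' From three fragment libraries to per-site and per-group statistics:
#' (1) build center-weighted occupancy tracks for the in vivo, in vitro
#' and naked-DNA libraries and normalize each by its dataset average;
#' (2) fit the log-quadratic GC-bias model on the naked control and apply
#' the per-bp correction to the in vivo and in vitro tracks; (3) scan the
#' region sequences for motif matches, classify them as functional from
#' ChIP occupancy, average the adjusted occupancy over each site and take
#' log2 in vivo / in vitro fold changes; (4) summarize by (gene class,
#' functional) group and run the functional-vs-nonfunctional z-test.
#'
#' @param invivo,invitro,naked fragment data.frames (see
#'   [read_fragments()]).
#' @param regions region data.frame from [read_regions()].
#' @param seqs named character vector of region sequences.
#' @param motif a `motif_matrix`.
#' @param chip ChIP table (`site_id`, `oct4`, `sox2`).
#' @param classes region-to-class map (`region`, `gene_class`).
#' @param threshold PWM relative-score threshold.
#' @param cutoff functional ChIP cutoff.
#' @param kernel a [center_kernel()].
#' @param gc_correct set FALSE to skip the GC model/correction stage (the
#'   normalized tracks are then floored at 0.01 and staged gc_adjusted
#'   unchanged otherwise).
#' @return List with `tracks` (named list of gc_adjusted tracks),
#'   `gc_model`, `sites` (per-site summaries), `groups_invivo`,
#'   `groups_invitro`, `test_functional` (z-test on in vivo per-site
#'   averages, functional vs nonfunctional; NULL when either group has
#'   fewer than 2 sites).
#' @export
run_pipeline <- function(invivo, invitro, naked, regions, seqs, motif,
                         chip, classes, threshold = 0.8, cutoff = 20,
                         kernel = center_kernel(), gc_correct = TRUE) {
  norm <- function(fr, lab)
    normalize_track(build_occupancy(fr, regions, kernel,
                                    dataset_label = lab))
  t_vivo <- norm(invivo, "invivo")
  t_vitro <- norm(invitro, "invitro")
  model <- NULL
  if (gc_correct) {
    t_naked <- norm(naked, "naked")
    model <- fit_gc_model(build_bin_table(t_naked, seqs))
    t_vivo <- apply_gc_correction(t_vivo, seqs, model)
    t_vitro <- apply_gc_correction(t_vitro, seqs, model)
  } else {
    flatten <- function(tr) occupancy_track(
      tr$regions, lapply(tr$values, pmax, 0.01),
      stage = "gc_adjusted", dataset_label = tr$dataset_label)
    t_vivo <- flatten(t_vivo)
    t_vitro <- flatten(t_vitro)
  }
  sites <- scan_pwm_regions(seqs, motif, threshold)
  sites <- classify_sites(sites, chip, cutoff = cutoff, classes = classes)
  sites <- site_occupancy_summary(sites, t_vivo, t_vitro)
  test <- NULL
  if (sum(sites$functional) >= 2 && sum(!sites$functional) >= 2)
    test <- two_group_z(sites$invivo_avg[sites$functional],
                        sites$invivo_avg[!sites$functional])
  list(tracks = list(invivo = t_vivo, invitro = t_vitro),
       gc_model = model, sites = sites,
       groups_invivo = summarize_groups(sites, "invivo"),
       groups_invitro = summarize_groups(sites, "invitro"),
       test_functional = test)
}
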