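#' Default pipeline configuration
#'
#' Every threshold the pipeline uses, in one auditable place: contact and
#' binding-mode cutoff (4 Angstrom), occupancy first-shell cutoff
#' (6 Angstrom), hydrogen-bond criterion (3.5 Angstrom, 30 degrees),
#' contact persistence filter (1 percent of frames), quartet instability
#' cutoff (15 of 24 bonds), and the residue-name synonym table. Seeds are
#' mandatory manifest fields, not config defaults.
#'
#' @return nested named list.
#' @seealso [write_config()], [read_config()]
#' @export
default_config <- function() {
  list(
    thresholds = list(
      mode_cutoff = 4.0,
      occupancy_cutoff = 6.0,
      hbond_donor_acceptor_max = 3.5,
      hbond_h_angle_max = 30,
      min_lifetime = 0.01,
      instability_cutoff = 15,
      clash_distance = 2.0
    ),
    grid = list(spacing = 1.0, margin = 2.0),
    clustering = list(k = 50, perplexity = 30, max_iter = 400),
    contact_map = list(residue_offset = 196),
    synonyms = default_synonyms()
  )
}

#' Write / read a pipeline configuration (YAML)
#' @param config nested list as from [default_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` the list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}
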