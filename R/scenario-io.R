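# YAML serialization of scenario specifications, so a study's generator
# conditions can live in a config file next to its pipeline config.

sel_to_list <- function(sel) {
  list(chain = sel$chain, ranges = lapply(sel$res_ranges, as.integer),
       atoms = sel$atom_names)
}

sel_from_list <- function(x) {
  select_atoms(x$chain, lapply(x$ranges, unlist), atom_names = unlist(x$atoms))
}

#' Write a scenario specification as YAML
#' @param spec a [scenario_spec()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  x <- unclass(spec)
  if (!is.null(x$mobile_domain)) x$mobile_domain$sel <- sel_to_list(x$mobile_domain$sel)
  if (!is.null(x$disordered)) x$disordered$sel <- sel_to_list(x$disordered$sel)
  if (!is.null(x$extra_atoms)) {
    x$extra_atoms <- lapply(seq_len(nrow(x$extra_atoms)), function(i)
      as.list(x$extra_atoms[i, ]))
  }
  yaml::write_yaml(x, path, precision = 12)
  invisible(path)
}

#' Read a scenario specification from YAML
#' @param path path written by [write_scenario()].
#' @return A [scenario_spec()].
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$mobile_domain)) {
    x$mobile_domain$sel <- sel_from_list(x$mobile_domain$sel)
    for (f in c("axis", "rotation_deg", "translation_A", "translation_dir", "pivot")) {
      if (!is.null(x$mobile_domain[[f]])) x$mobile_domain[[f]] <- unlist(x$mobile_domain[[f]])
    }
  }
  if (!is.null(x$disordered)) x$disordered$sel <- sel_from_list(x$disordered$sel)
  if (!is.null(x$extra_atoms)) {
    x$extra_atoms <- do.call(rbind, lapply(x$extra_atoms, as.data.frame))
  }
  unvec <- function(prog, fields) {
    for (f in fields) if (!is.null(prog[[f]])) prog[[f]] <- unlist(prog[[f]])
    prog
  }
  x$contacts <- lapply(x$contacts %||% list(), unvec,
                       fields = c("res_a", "res_b", "p", "direction"))
  x$hbonds <- lapply(x$hbonds %||% list(), unvec,
                     fields = c("donor", "acceptor", "p", "direction"))
  x$mixtures <- lapply(x$mixtures %||% list(), unvec,
                       fields = c("res_a", "res_b", "weights", "means", "sds", "direction"))
  if (!is.null(x$salt_bridge)) {
    x$salt_bridge <- unvec(x$salt_bridge,
                           c("p_res", "arg_res", "lys_res", "anchor", "p_states"))
  }
  scenario_spec(seed = x$seed, n_frames = x$n_frames, dt_ns = x$dt_ns,
                helices = lapply(x$helices, unvec, fields = c("origin", "axis")),
                segments = lapply(x$segments %||% list(), unvec, fields = c("origin", "axis")),
                extra_atoms = x$extra_atoms, mobile_domain = x$mobile_domain,
                disordered = x$disordered, contacts = x$contacts,
                hbonds = x$hbonds, mixtures = x$mixtures,
                salt_bridge = x$salt_bridge)
}
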