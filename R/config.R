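#' Read a declarative run configuration
#'
#' Run configurations are YAML documents with the sections
#' `fragments` (list of fragment specs: `kind`, `sites`, optional
#' `mutations`, `n_copies`), `nonbonded` (`delta`, `switch_on`,
#' `cutoff`, `dielectric`), `grouping` (`cutoff`, `max_groups`),
#' `anchors` (`bridge_k`, `label_k`), `histogram` (`K`, `sigma`,
#' `bin_width`, `n_bins`) and `protocol` (list of stages with `mode`,
#' `n_steps`, `temperature`, `dt`, `friction`).  Missing keys take the
#' package defaults.
#'
#' @param path path to a YAML config file
#' @return a validated config list
#' @seealso [defaultRunConfig()], [buildFromConfig()]
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  .mergeConfig(defaultRunConfig(), cfg)
}

#' @rdname readRunConfig
#' @export
defaultRunConfig <- function() {
  list(
    fragments = list(),
    nonbonded = list(delta = 1, switch_on = 10, cutoff = 12,
                     dielectric = 1),
    grouping = list(cutoff = 12, max_groups = 255L),
    anchors = list(bridge_k = 50, label_k = 10),
    histogram = list(K = 500, sigma = 1.1, bin_width = 1, n_bins = 60L),
    protocol = list(
      list(mode = "minimize", n_steps = 1000L),
      list(mode = "dynamics", n_steps = 10000L, temperature = 300,
           dt = 1, friction = 5))
  )
}

.mergeConfig <- function(defaults, cfg) {
  if (is.null(cfg)) return(defaults)
  for (key in names(cfg)) {
    if (key %in% c("fragments", "protocol") || !is.list(cfg[[key]]) ||
        is.null(defaults[[key]]))
      defaults[[key]] <- cfg[[key]]
    else
      defaults[[key]] <- utils::modifyList(defaults[[key]], cfg[[key]])
  }
  defaults
}

#' Instantiate fragments and restraints from a configuration
#'
#' Builds every fragment spec in the config against the given host
#' system: bridge kinds via [buildBridgeFragment] with their bridge and
#' anchor restraints, label kinds via [buildLabelFragment].  Label
#' copies are grouped with [groupFragments] when their total count
#' exceeds the configured `max_groups`.
#'
#' @param system host [AtomicSystem]
#' @param config config list from [readRunConfig]
#' @param seed integer seed for label copy spreading
#' @return list with the updated `system`, `fragments` (bridges),
#'   `ensembles` (labels), combined `restraints` and `grouping` info
#'   (NULL when no grouping was needed)
#' @export
buildFromConfig <- function(system, config, seed = 1L) {
  fragments <- list()
  ensembles <- list()
  restraints <- list()
  for (fs in config$fragments) {
    spec <- fragmentSpec(fs$kind, sites = unlist(fs$sites),
                         mutations = fs$mutations,
                         nCopies = if (is.null(fs$n_copies)) 1L
                                   else fs$n_copies)
    if (spec$kind %in% c("mtssl_label", "dummy_label")) {
      res <- buildLabelFragment(system, spec, seed = seed)
      system <- res$system
      ensembles[[length(ensembles) + 1L]] <- res$ensemble
      for (f in res$ensemble@copies)
        restraints[[length(restraints) + 1L]] <-
          anchorRestraints(f, k = config$anchors$label_k)
    } else {
      res <- buildBridgeFragment(system, spec)
      system <- res$system
      fragments[[length(fragments) + 1L]] <- res$fragment
      restraints[[length(restraints) + 1L]] <-
        metalBridgeRestraints(spec$kind, res$fragment, system)
      restraints[[length(restraints) + 1L]] <-
        anchorRestraints(res$fragment, k = config$anchors$bridge_k)
    }
  }
  grouping <- NULL
  nCopiesTotal <- sum(vapply(ensembles, function(e)
    length(e@copies), 1L))
  if (nCopiesTotal > config$grouping$max_groups) {
    grouping <- groupFragments(system, ensembles,
                               cutoff = config$grouping$cutoff,
                               maxGroups = config$grouping$max_groups)
    system <- grouping$system
    ensembles <- grouping$ensembles
  }
  list(system = system, fragments = fragments, ensembles = ensembles,
       restraints = if (length(restraints))
         do.call(combineRestraints, restraints) else NULL,
       grouping = grouping)
}
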