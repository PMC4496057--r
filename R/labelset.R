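#' Construct a label set
#'
#' A label set is the controlled vocabulary for point annotations: an ordered
#' vector of label names, optional named label groups (functional groups such
#' as coral or turf algae, used for binary agreement statistics), and optional
#' dataset-scoped remapping rules that translate legacy labels into the
#' vocabulary at read time.
#'
#' @param labels character vector of unique label names; the order is
#'   meaningful (it fixes score-vector columns and argmax tie-breaking).
#' @param groups named list of character vectors; every member must be a
#'   declared label.
#' @param remaps named list of remap presets. Each preset is a named character
#'   vector `c(source = target)`; targets must be declared labels. Sources may
#'   be legacy labels outside the vocabulary.
#' @return an object of class `labelset`.
#' @examples
#' ls <- labelset(c("Coral", "Sand"), groups = list(coral = "Coral"))
#' @export
labelset <- function(labels, groups = list(), remaps = list()) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    abort_reefpoint("label names must be unique", "labelset_error")
  }
  if (length(labels) == 0L) {
    abort_reefpoint("a label set needs at least one label", "labelset_error")
  }
  groups <- lapply(groups, as.character)
  for (g in names(groups)) {
    bad <- setdiff(groups[[g]], labels)
    if (length(bad)) {
      abort_reefpoint(
        sprintf("group '%s' contains undeclared labels: %s",
                g, paste(bad, collapse = ", ")),
        "labelset_error"
      )
    }
  }
  for (r in names(remaps)) {
    tgt <- unname(remaps[[r]])
    bad <- setdiff(tgt, labels)
    if (length(bad)) {
      abort_reefpoint(
        sprintf("remap '%s' targets undeclared labels: %s",
                r, paste(bad, collapse = ", ")),
        "labelset_error"
      )
    }
  }
  structure(
    list(labels = labels, groups = groups, remaps = remaps),
    class = "labelset"
  )
}

#' @export
print.labelset <- function(x, ...) {
  cat("<labelset> ", length(x$labels), " labels\n", sep = "")
  cat("  labels: ", paste(x$labels, collapse = ", "), "\n", sep = "")
  if (length(x$groups)) {
    cat("  groups: ", paste(names(x$groups), collapse = ", "), "\n", sep = "")
  }
  if (length(x$remaps)) {
    cat("  remap presets: ", paste(names(x$remaps), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' The consensus benthic label set
#'
#' The 20-label consensus vocabulary used for multi-location reef surveys:
#' 8 scleractinian genera plus a generic hard-coral label, the hydrozoan
#' Millepora, sponges, soft coral, three algal functional groups (macroalgae,
#' crustose coralline algae, turf algae), sand, bare space, transect
#' hardware, an 'Unclear' label and a catch-all.
#'
#' Groups: `coral` (the 8 genera plus 'Other scleractinians'), `macroalgae`,
#' `CCA`, `turf`, and `algae` (the three algal groups combined).
#'
#' Remap presets: `moorea_bare_space` (Bare space -> Crustose coralline
#' algae, for locations where bare rock is effectively CCA-covered) and
#' `heron_coral_collapse` (all coral genera -> 'Other scleractinians', for
#' archives that never resolved corals to genus).
#'
#' @return a [labelset] with 20 labels.
#' @export
consensus_labelset <- function() {
  genera <- c("Acropora", "Favia", "Favites", "Montastraea", "Pavona",
              "Platygyra", "Pocillopora", "Porites")
  labels <- c(
    genera,
    "Other scleractinians",
    "Millepora",
    "Sponges",
    "Soft coral",
    "Crustose coralline algae",
    "Turf algae",
    "Macroalgae",
    "Sand",
    "Bare space",
    "Transect hardware",
    "Unclear",
    "All other labels"
  )
  groups <- list(
    coral      = c(genera, "Other scleractinians"),
    macroalgae = "Macroalgae",
    CCA        = "Crustose coralline algae",
    turf       = "Turf algae",
    algae      = c("Macroalgae", "Crustose coralline algae", "Turf algae")
  )
  remaps <- list(
    moorea_bare_space = c("Bare space" = "Crustose coralline algae"),
    heron_coral_collapse = stats::setNames(
      rep("Other scleractinians", length(genera)), genera
    )
  )
  labelset(labels, groups, remaps)
}

#' Read a label set from a YAML or JSON config file
#'
#' The config must have a `labels` key (ordered list) and may have `groups`
#' (mapping of group name to member list) and `remaps` (mapping of preset
#' name to source: target pairs).
#'
#' @param path path to a `.yml`/`.yaml`/`.json` file.
#' @return a [labelset].
#' @export
read_labelset <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$labels)) {
    abort_reefpoint("label-set config must contain a 'labels' key",
                    "format_error")
  }
  remaps <- lapply(cfg$remaps %||% list(), function(r) unlist(r))
  labelset(unlist(cfg$labels), cfg$groups %||% list(), remaps)
}

#' Write a label set to a YAML config file
#'
#' @param x a [labelset].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labelset <- function(x, path) {
  stopifnot(inherits(x, "labelset"))
  yaml::write_yaml(
    list(labels = x$labels, groups = x$groups,
         remaps = lapply(x$remaps, as.list)),
    path
  )
  invisible(path)
}

#' Resolve a label group
#'
#' Accepts either a group name declared in the label set or an explicit
#' character vector of member labels.
#'
#' @param label_set a [labelset].
#' @param group group name or character vector of labels.
#' @return character vector of member labels.
#' @export
label_group <- function(label_set, group) {
  stopifnot(inherits(label_set, "labelset"))
  if (length(group) == 1L && group %in% names(label_set$groups)) {
    return(label_set$groups[[group]])
  }
  bad <- setdiff(group, label_set$labels)
  if (length(bad)) {
    abort_reefpoint(
      sprintf("unknown group or labels: %s", paste(bad, collapse = ", ")),
      "labelset_error"
    )
  }
  as.character(group)
}
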