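## Lipid topology: the per-lipid atom-name map every analysis selection
## resolves against. Atom identity comes solely from names (no force-field
## topology parsing).

#' Define a per-lipid atom topology
#'
#' A `lipid_topology` describes one lipid species by name: how many atoms a
#' molecule has, where each named atom sits inside the molecule, and which
#' named selections the analyses use (tails, headgroup, glycerol vector,
#' splay vertex, three-particle-correlation selection, hydrogen-bond donor
#' and acceptor groups).
#'
#' @param lipid_name residue name, e.g. `"MMG"`.
#' @param atom_names character vector of all atom names of one molecule, in
#'   file order; defines `atoms_per_lipid` and the name map.
#' @param tail1_atoms,tail2_atoms ordered carbon names of the two hydrocarbon
#'   tails (first to terminal carbon).
#' @param headgroup_atoms names of the hydrophilic moiety.
#' @param glycerol_vector_atoms two atom names spanning the glycerol
#'   orientation vector (default `c("C1","C3")`).
#' @param splay_vertex branching carbon at which splay angles are measured.
#' @param g3_selection atom names used for the three-particle correlation
#'   fingerprint (lipid-acid carbons, carbonyl carbon excluded).
#' @param carbonyl_atom name of the carbonyl carbon, which must not appear
#'   in `g3_selection` (default none).
#' @param donors list of length-2 character vectors `c(oxygen, hydrogen)` for
#'   hydroxyl donor groups.
#' @param acceptors names of acceptor oxygens.
#' @param stereo_label optional stereochemistry tag per molecule type, one of
#'   `"2R3S"`, `"2S3R"`, `"2R3R"`, `"2S3S"`.
#' @return object of class `lipid_topology`.
#' @export
lipid_topology <- function(lipid_name, atom_names, tail1_atoms, tail2_atoms,
                           headgroup_atoms,
                           glycerol_vector_atoms = c("C1", "C3"),
                           splay_vertex = "C5",
                           g3_selection = NULL,
                           carbonyl_atom = NA_character_,
                           donors = list(),
                           acceptors = character(),
                           stereo_label = NA_character_) {
  stopifnot(is.character(atom_names), length(atom_names) >= 3,
            !anyDuplicated(atom_names))
  name_map <- stats::setNames(seq_along(atom_names), atom_names)
  need <- unique(c(tail1_atoms, tail2_atoms, headgroup_atoms,
                   glycerol_vector_atoms, splay_vertex, g3_selection,
                   unlist(donors), acceptors))
  missing <- setdiff(need, atom_names)
  if (length(missing) > 0) {
    stop("topology error: atom name(s) not in name map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(intersect(tail1_atoms, tail2_atoms)) > 0) {
    stop("topology error: tail1 and tail2 share atoms", call. = FALSE)
  }
  if (!is.na(carbonyl_atom) && carbonyl_atom %in% g3_selection) {
    stop("topology error: g3 selection must exclude the carbonyl carbon ",
         carbonyl_atom, call. = FALSE)
  }
  if (!is.na(stereo_label) &&
      !stereo_label %in% c("2R3S", "2S3R", "2R3R", "2S3S")) {
    stop("topology error: unknown stereo label ", stereo_label, call. = FALSE)
  }
  structure(list(
    lipid_name = lipid_name,
    atoms_per_lipid = length(atom_names),
    atom_names = atom_names,
    name_map = name_map,
    tail1_atoms = tail1_atoms,
    tail2_atoms = tail2_atoms,
    headgroup_atoms = headgroup_atoms,
    glycerol_vector_atoms = glycerol_vector_atoms,
    splay_vertex = splay_vertex,
    g3_selection = g3_selection %||% character(),
    carbonyl_atom = carbonyl_atom,
    donors = donors,
    acceptors = acceptors,
    stereo_label = stereo_label
  ), class = "lipid_topology")
}

#' Default two-tailed glycerolipid topology
#'
#' The 43-atom model lipid used by the synthetic generator, following the
#' standard MMG atom numbering: glycerol carbons C1-C3 with the primary
#' hydroxyl O1, carbonyl carbon C4 with O2, ester O4, branching carbon C5,
#' beta carbon C6 carrying the O5 hydroxyl, tail 1 = C7-C20, tail 2 =
#' C21-C35, hydroxyl hydrogens HO1/HO3/HO5. The three-particle-correlation
#' selection is the lipid-acid carbons C5-C35 (C4 excluded).
#'
#' @param stereo_label optional stereochemistry tag.
#' @return a [lipid_topology()].
#' @export
mmg_topology <- function(stereo_label = "2R3S") {
  atoms <- c(paste0("C", 1:35), paste0("O", 1:5), "HO1", "HO3", "HO5")
  lipid_topology(
    lipid_name = "MMG",
    atom_names = atoms,
    tail1_atoms = paste0("C", 7:20),
    tail2_atoms = paste0("C", 21:35),
    headgroup_atoms = c(paste0("C", 1:6), paste0("O", 1:5)),
    glycerol_vector_atoms = c("C1", "C3"),
    splay_vertex = "C5",
    g3_selection = paste0("C", 5:35),
    carbonyl_atom = "C4",
    donors = list(c("O1", "HO1"), c("O3", "HO3"), c("O5", "HO5")),
    acceptors = paste0("O", 1:5),
    stereo_label = stereo_label
  )
}

#' Read a lipid topology from a YAML or JSON config file
#'
#' The file must provide `lipid_name`, `atom_names`, `tail1_atoms`,
#' `tail2_atoms` and `headgroup_atoms`; the remaining fields are optional and
#' default as in [lipid_topology()].
#'
#' @param path file path (`.yml`/`.yaml`/`.json`).
#' @return a [lipid_topology()].
#' @export
read_lipid_topology <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  donors <- lapply(cfg$donors %||% list(), unlist)
  lipid_topology(
    lipid_name = cfg$lipid_name,
    atom_names = unlist(cfg$atom_names),
    tail1_atoms = unlist(cfg$tail1_atoms),
    tail2_atoms = unlist(cfg$tail2_atoms),
    headgroup_atoms = unlist(cfg$headgroup_atoms),
    glycerol_vector_atoms = unlist(cfg$glycerol_vector_atoms %||% c("C1", "C3")),
    splay_vertex = cfg$splay_vertex %||% "C5",
    g3_selection = unlist(cfg$g3_selection %||% NULL),
    carbonyl_atom = cfg$carbonyl_atom %||% NA_character_,
    donors = donors,
    acceptors = unlist(cfg$acceptors %||% character()),
    stereo_label = cfg$stereo_label %||% NA_character_
  )
}

#' @export
print.lipid_topology <- function(x, ...) {
  cat("<lipid_topology> ", x$lipid_name, ": ", x$atoms_per_lipid,
      " atoms/lipid; tails ", length(x$tail1_atoms), "+",
      length(x$tail2_atoms), " C; g3 selection ", length(x$g3_selection),
      " atoms\n", sep = "")
  invisible(x)
}

#' Resolve atom names to within-lipid indices
#' @noRd
resolve_atoms <- function(topology, names) {
  idx <- topology$name_map[names]
  if (anyNA(idx)) {
    stop("topology error: cannot resolve atom(s): ",
         paste(names[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  unname(idx)
}
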