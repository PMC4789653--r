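# Conformer classification of the Mana1-6Man arm and survey statistics.
#
# The global conformation of a biantennary glycan is summarised by the
# (phi, psi, omega) triple of the Mana1-6Man linkage and assigned to the
# nearest of five reference conformers from replica-exchange MD, using
# Euclidean distance on wrapped angular differences (the toroidal metric).

#' The five reference conformers
#'
#' Reference (phi, psi, omega) triples for the Mana1-6Man linkage, in the
#' fixed order used for tie-breaking.
#'
#' @return data.frame with columns `name`, `phi`, `psi`, `omega` (degrees).
#' @export
reference_conformers <- function() {
  data.frame(
    name = c("half-back-fold", "tight-back-fold", "back-fold",
             "extend-a", "extend-b"),
    phi   = c(70, 70, 70, 70, 70),
    psi   = c(60, 60, 90, 180, 180),
    omega = c(60, 180, 60, 60, 180),
    stringsAsFactors = FALSE
  )
}

#' Toroidal Euclidean distance between torsion triples
#'
#' `sqrt(sum(d^2))` where each `d` is the componentwise angular difference
#' wrapped into (-180, 180]. Wrapping makes the metric continuous across the
#' +-180 seam (e.g. omega = -179 vs 180 differ by 1, not 359).
#'
#' @param a,b numeric angle vectors of equal length (degrees).
#' @return distance in degrees.
#' @export
toroidal_distance <- function(a, b) {
  stopifnot(length(a) == length(b), all(is.finite(a)), all(is.finite(b)))
  sqrt(sum(wrap_angle(a - b)^2))
}

#' Classify a Mana1-6Man torsion triple
#'
#' Nearest-reference assignment under the toroidal metric; the triple is
#' `"unclassified"` when no reference lies within the cutoff. Exact ties
#' resolve to the reference listed first in [reference_conformers()].
#'
#' @param triple numeric `c(phi, psi, omega)` in degrees.
#' @param references reference table, see [reference_conformers()].
#' @param cutoff classification radius in degrees (default 45).
#' @return object of class `conformer_assignment`: list with `class_label`,
#'   `distance_deg` (to the nearest reference), `nearest` and `runner_up`
#'   (name + distance of the second-nearest reference).
#' @export
classify_conformer <- function(triple, references = reference_conformers(),
                               cutoff = 45) {
  if (is.null(references) || nrow(references) == 0)
    stop("reference conformer set is empty")
  stopifnot(length(triple) == 3)
  d <- vapply(seq_len(nrow(references)), function(i)
    toroidal_distance(triple,
                      c(references$phi[i], references$psi[i],
                        references$omega[i])), numeric(1))
  ord <- order(d)  # stable: ties keep reference order
  nearest <- ord[1]
  structure(list(
    class_label = if (d[nearest] <= cutoff) references$name[nearest]
                  else "unclassified",
    distance_deg = d[nearest],
    nearest = references$name[nearest],
    runner_up = list(name = references$name[ord[2]],
                     distance_deg = d[ord[2]])),
    class = "conformer_assignment")
}

#' @export
print.conformer_assignment <- function(x, ...) {
  cat(sprintf("%s (distance %.2f deg to %s; runner-up %s at %.2f)\n",
              x$class_label, x$distance_deg, x$nearest,
              x$runner_up$name, x$runner_up$distance_deg))
  invisible(x)
}

#' Circular mean and spread of angles
#'
#' Mean direction by atan2 of the mean sine and cosine; the spread is the
#' root-mean-square of deviations from that mean, each deviation wrapped
#' into (-180, 180]. For tight clusters away from the seam this coincides
#' with the arithmetic mean +- SD.
#'
#' @param angles numeric vector of angles in degrees (n >= 1).
#' @return list with `mean_deg` (in (-180, 180]), `sd_deg`, `n`.
#' @export
circular_mean_sd <- function(angles) {
  angles <- angles[is.finite(angles)]
  n <- length(angles)
  if (n < 1) stop("need at least one finite angle")
  rad <- angles * pi / 180
  s <- mean(sin(rad)); c_ <- mean(cos(rad))
  if (sqrt(s^2 + c_^2) < 1e-9)
    stop("circular mean undefined: zero resultant (uniformly spread angles)")
  m <- wrap_angle(atan2(s, c_) * 180 / pi)
  sd <- sqrt(mean(wrap_angle(angles - m)^2))
  list(mean_deg = m, sd_deg = sd, n = n)
}

#' Construct a survey dataset entry
#'
#' Bundles one glycan's identity, torsions and conformer assignment for use
#' in [dataset_report()].
#'
#' @param structure_id unique identifier (e.g. PDB code plus glycan id).
#' @param torsions torsion table from [linkage_torsions()].
#' @param bisected logical: does the glycan carry a bisecting GlcNAc?
#' @param source_category `"lectin/antibody complex"`, `"glycoprotein"`, or
#'   NA.
#' @param cutoff classification radius passed to [classify_conformer()].
#' @return object of class `dataset_entry`.
#' @export
dataset_entry <- function(structure_id, torsions, bisected,
                          source_category = NA_character_, cutoff = 45) {
  a16 <- torsions[torsions$linkage_type == "a1-6", , drop = FALSE]
  assignment <- NULL
  rotamer <- NA_character_
  if (nrow(a16) == 1 && all(is.finite(c(a16$phi, a16$psi, a16$omega)))) {
    assignment <- classify_conformer(c(a16$phi, a16$psi, a16$omega),
                                     cutoff = cutoff)
    rotamer <- omega_rotamer(a16$omega)
  }
  structure(list(structure_id = structure_id, torsions = torsions,
                 bisected = bisected, source_category = source_category,
                 assignment = assignment, rotamer = rotamer),
            class = "dataset_entry")
}

entry_angles <- function(entry) {
  ts <- entry$torsions
  a13 <- ts[ts$linkage_type == "a1-3", , drop = FALSE]
  a16 <- ts[ts$linkage_type == "a1-6", , drop = FALSE]
  c(phi_a13 = if (nrow(a13)) a13$phi[1] else NA_real_,
    psi_a13 = if (nrow(a13)) a13$psi[1] else NA_real_,
    phi_a16 = if (nrow(a16)) a16$phi[1] else NA_real_,
    psi_a16 = if (nrow(a16)) a16$psi[1] else NA_real_,
    omega_a16 = if (nrow(a16)) a16$omega[1] else NA_real_)
}

#' Survey report over a glycan dataset
#'
#' Computes, per group (bisected / non-bisected), the circular mean and
#' spread of the Mana1-3Man and Mana1-6Man torsions, conformer class counts,
#' omega rotamer counts, and 0-360 histograms of the Mana1-6Man angles.
#'
#' @param entries list of `dataset_entry` objects.
#' @param bin_width histogram bin width in degrees (default 15).
#' @return object of class `glycan_dataset_report`: list with `per_entry`
#'   (data.frame), `group_stats`, `class_counts`, `rotamer_counts`,
#'   `histograms`.
#' @export
dataset_report <- function(entries, bin_width = 15) {
  stopifnot(length(entries) >= 1)
  ids <- vapply(entries, `[[`, "", "structure_id")
  if (anyDuplicated(ids))
    stop("duplicate structure_id in dataset: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  per <- do.call(rbind, lapply(entries, function(e) {
    ang <- entry_angles(e)
    data.frame(structure_id = e$structure_id,
               bisected = e$bisected,
               source_category = e$source_category,
               t(ang),
               class_label = if (is.null(e$assignment)) NA_character_
                             else e$assignment$class_label,
               distance_deg = if (is.null(e$assignment)) NA_real_
                              else e$assignment$distance_deg,
               rotamer = e$rotamer,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  groups <- split(seq_along(entries), ifelse(per$bisected, "bisected",
                                             "non-bisected"))
  angle_cols <- c("phi_a13", "psi_a13", "phi_a16", "psi_a16", "omega_a16")
  group_stats <- lapply(groups, function(idx) {
    stats_ <- lapply(angle_cols, function(col) {
      v <- per[[col]][idx]
      v <- v[is.finite(v)]
      if (length(v) == 0) return(NULL)
      circular_mean_sd(v)
    })
    names(stats_) <- angle_cols
    stats_
  })
  class_counts <- lapply(groups, function(idx)
    table(per$class_label[idx], useNA = "no"))
  rotamer_counts <- lapply(groups, function(idx)
    table(per$rotamer[idx], useNA = "no"))
  breaks <- seq(0, 360, by = bin_width)
  histograms <- lapply(groups, function(idx) {
    h <- lapply(c("phi_a16", "psi_a16", "omega_a16"), function(col) {
      v <- per[[col]][idx]
      v <- v[is.finite(v)] %% 360
      graphics::hist(v, breaks = breaks, plot = FALSE)$counts
    })
    names(h) <- c("phi_a16", "psi_a16", "omega_a16")
    h
  })
  structure(list(per_entry = per, group_stats = group_stats,
                 class_counts = class_counts,
                 rotamer_counts = rotamer_counts,
                 histograms = histograms,
                 bin_width = bin_width),
            class = "glycan_dataset_report")
}

#' @export
print.glycan_dataset_report <- function(x, ...) {
  cat("Glycan conformer survey:", nrow(x$per_entry), "entries\n")
  for (g in names(x$group_stats)) {
    st <- x$group_stats[[g]]
    cat(sprintf("  %s (n = %d):\n", g,
                sum((x$per_entry$bisected) == (g == "bisected"))))
    for (a in names(st)) {
      if (is.null(st[[a]])) next
      cat(sprintf("    %-9s %6.0f +- %.0f\n", a, st[[a]]$mean_deg,
                  st[[a]]$sd_deg))
    }
    cc <- x$class_counts[[g]]
    if (length(cc))
      cat("    classes:",
          paste(sprintf("%s=%d", names(cc), as.integer(cc)), collapse = " "),
          "\n")
  }
  invisible(x)
}
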