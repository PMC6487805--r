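#' Run the full target-selection workflow on an alignment
#'
#' End-to-end driver: reads the grouped alignment, classifies every column,
#' then for every taxon group builds the sliding-window density profile,
#' renders its plot, selects the candidate target region (the whole alignment
#' when no window reaches the threshold and the alignment fits the size
#' limit), and writes the masked primer-design input; the processed alignment
#' is written once. All outputs land in `out_dir/project_id` together with a
#' `manifest.tsv`; on any error partial outputs are removed.
#'
#' @param input Alignment file path or text (see [read_alignment()]).
#' @param format `"auto"`, `"clustal"` or `"fasta"`.
#' @param delimiter Header field delimiter (default em-dash).
#' @param fragment_len Fragment width in columns (default 20).
#' @param window_bp Sliding-window span in columns (default 300); must be an
#'   odd multiple of `fragment_len`.
#' @param threshold Minimum average mutation index for region selection
#'   (default 2).
#' @param max_region_len Maximum exported region length in columns
#'   (default 2000).
#' @param line_endings `"unix"` or `"windows"` for all text outputs.
#' @param plot_formats Graphic formats to render (default all five).
#' @param out_dir Output directory (default `"."`).
#' @param project_id Project token naming the output directory; default a
#'   random 8-hex-character ID. Pin it for reproducible output paths.
#' @param zip Also pack the project directory into a ZIP archive.
#' @param overwrite Replace an existing project directory.
#' @param log_level One of `"debug"`, `"info"`, `"warn"`, `"error"`,
#'   `"quiet"`.
#' @return Invisibly, the manifest tibble (`file`, `type`, `group`) with the
#'   project directory as attribute `project_dir`.
#' @export
run_catch <- function(input,
                      format = "auto",
                      delimiter = "—",
                      fragment_len = 20,
                      window_bp = 300,
                      threshold = 2,
                      max_region_len = 2000,
                      line_endings = "unix",
                      plot_formats = c("eps", "pdf", "png", "svg", "tiff"),
                      out_dir = ".",
                      project_id = NULL,
                      zip = FALSE,
                      overwrite = FALSE,
                      log_level = "info") {
  old <- options(taxamark.log_level = log_level)
  on.exit(options(old), add = TRUE)
  if (window_bp %% fragment_len != 0 ||
      (window_bp %/% fragment_len) %% 2 != 1) {
    tm_abort(sprintf(
      "window_bp (%d) must be an odd multiple of fragment_len (%d)",
      window_bp, fragment_len), "parameter")
  }
  project_id <- project_id %||%
    paste(sample(c(0:9, letters[1:6]), 8, replace = TRUE), collapse = "")
  dest <- file.path(out_dir, project_id)
  if (file.exists(dest) && !overwrite) {
    tm_abort(sprintf(
      "project '%s' already exists under '%s'; use overwrite to replace it",
      project_id, out_dir), "collision")
  }
  if (file.exists(dest)) unlink(dest, recursive = TRUE)
  dir.create(dest, recursive = TRUE)
  cleanup <- TRUE
  on.exit(if (cleanup) unlink(dest, recursive = TRUE), add = TRUE)

  aln <- read_alignment(input, format = format, delimiter = delimiter)
  tm_log("info", sprintf("alignment: %d records, %d columns, %d groups",
                         nrow(aln$records), aln$n_columns, length(aln$groups)))
  verdicts <- classify_alignment(aln)

  manifest <- list()
  note <- function(file, type, group) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      file = basename(file), type = type, group = group)
  }

  proc_path <- file.path(dest, sprintf("%s_processed_alignment.txt", project_id))
  write_processed_alignment(aln, verdicts, proc_path,
                            fragment_len = fragment_len,
                            line_endings = line_endings)
  note(proc_path, "processed_alignment", NA_character_)

  profiles <- lapply(names(aln$groups), function(g) {
    build_profile(verdicts, g, fragment_len = fragment_len,
                  window_bp = window_bp)
  })
  names(profiles) <- names(aln$groups)

  for (g in names(aln$groups)) {
    prof <- profiles[[g]]
    tab_path <- file.path(dest, sprintf("%s_%s_profile.tsv", project_id,
                                        sanitize_label(g)))
    write_profile_table(prof, tab_path, line_endings = line_endings)
    note(tab_path, "profile_table", g)

    plot_files <- render_profile_plot(profiles, dest, project_id, focal = g,
                                      formats = plot_formats,
                                      threshold = threshold)
    for (pf in plot_files) note(pf, "plot", g)

    region <- select_target_region(prof, threshold = threshold,
                                   max_len = max_region_len)
    if (nrow(region) == 0) {
      if (aln$n_columns <= max_region_len) {
        tm_log("info", sprintf(
          "no window reaches index %.3g for '%s'; exporting the whole alignment",
          threshold, g))
        region <- c(1L, aln$n_columns)
      } else {
        tm_abort(sprintf(
          paste0("no window reaches average mutation index %.3g for group '%s' ",
                 "and the %d-column alignment exceeds the %d-column export ",
                 "limit; inspect the profile table and pick a region"),
          threshold, g, aln$n_columns, max_region_len), "size")
      }
    }
    target_path <- file.path(dest, sprintf("%s_%s_primerexplorer_input.txt",
                                           project_id, sanitize_label(g)))
    make_primerexplorer_input(aln, verdicts, g, region, path = target_path,
                              line_endings = line_endings)
    note(target_path, "masked_target", g)
  }

  manifest <- dplyr::bind_rows(manifest)
  man_path <- file.path(dest, "manifest.tsv")
  write_text(c(paste("file", "type", "group", sep = "\t"),
               paste(manifest$file, manifest$type,
                     ifelse(is.na(manifest$group), "", manifest$group),
                     sep = "\t")),
             man_path, line_endings)

  if (zip) {
    zip_path <- file.path(out_dir, paste0(project_id, ".zip"))
    if (file.exists(zip_path) && !overwrite) {
      tm_abort(sprintf("archive '%s' already exists", zip_path), "collision")
    }
    write_zip_archive(zip_path, dir = dest, root = project_id)
    tm_log("info", sprintf("archive written: %s", zip_path))
  }
  cleanup <- FALSE
  tm_log("info", sprintf("run complete: %d output files in %s",
                         nrow(manifest) + 1, dest))
  attr(manifest, "project_dir") <- dest
  invisible(manifest)
}
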