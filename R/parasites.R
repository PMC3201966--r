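# Parasite life cycles: tabular records, the stage-wise viability rule,
# trophic-link inference from parasitological records, and per-host
# parasite richness.

# Reserved host label for free-living stages (eggs, cercariae in the water
# column); treated as present in every web.
.ENV_HOST <- "environment"

#' Construct parasite life-cycle records
#'
#' @param table data.frame with columns `parasite`, `stage_index` (1 = first
#'   intermediate host stage, increasing to the definitive host),
#'   `stage_role` (free text, e.g. "intermediate" / "definitive"),
#'   `transmission` (how the stage is acquired: `trophic`, `direct` or
#'   `vector`), `hosts` (semicolon-separated suitable host labels; the
#'   reserved label `"environment"` marks a free-living stage) and `source`
#'   (`empirical` or `literature`).
#' @return a validated [ParasiteRecords-class].
#' @export
parasiteRecords <- function(table) {
  table$stage_index <- as.integer(table$stage_index)
  table <- table[order(table$parasite, table$stage_index), , drop = FALSE]
  rownames(table) <- NULL
  new("ParasiteRecords", table = table)
}

#' Read / write a parasite life-cycle table
#'
#' The CSV form of [ParasiteRecords-class]: one row per (parasite, stage).
#'
#' @param path CSV file.
#' @return [readParasiteTable()]: a [ParasiteRecords-class];
#'   [writeParasiteTable()]: `path`, invisibly.
#' @export
readParasiteTable <- function(path) {
  parasiteRecords(utils::read.csv(path, check.names = FALSE,
                                  colClasses = "character"))
}

#' @rdname readParasiteTable
#' @param records a [ParasiteRecords-class].
#' @export
writeParasiteTable <- function(records, path) {
  stopifnot(is(records, "ParasiteRecords"))
  utils::write.csv(records@table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# Nested-list view: per parasite, a list of stages with host sets and
# transmission modes.
.recordList <- function(records) {
  tab <- records@table
  lapply(split(tab, tab$parasite), function(d) {
    d <- d[order(d$stage_index), , drop = FALSE]
    list(stages = lapply(strsplit(d$hosts, ";", fixed = TRUE), trimws),
         transmission = d$transmission)
  })
}

#' Filter parasites to those viable in a web
#'
#' A parasite is viable in a web iff every life-cycle stage has at least one
#' suitable host present, and (under the default strict reading) every
#' trophically acquired stage transition is supported by at least one present
#' feeding link: some present host of stage s+1 must eat some present host of
#' stage s.  Transitions into or out of a free-living (`"environment"`) stage
#' are exempt from the trophic check.  Host labels never seen in the web are
#' treated as absent, with a warning.
#'
#' @param web a [FoodWeb-class].
#' @param records a [ParasiteRecords-class].
#' @param requireTrophicSupport if `FALSE`, relax to stage-wise host presence
#'   only (the looser reading of the viability rule).
#' @param warnUnknown emit the unknown-label warning (default `TRUE`).
#' @return the viable subset, as a [ParasiteRecords-class].
#' @export
filterViableParasites <- function(web, records, requireTrophicSupport = TRUE,
                                  warnUnknown = TRUE) {
  stopifnot(is(web, "FoodWeb"), is(records, "ParasiteRecords"))
  labels <- speciesLabels(web)
  a <- web@adj
  allHosts <- unique(unlist(strsplit(records@table$hosts, ";", fixed = TRUE)))
  allHosts <- trimws(allHosts)
  unknown <- setdiff(allHosts, c(labels, .ENV_HOST))
  if (length(unknown) && warnUnknown)
    warning("host labels not present in the web (treated as absent): ",
            paste(unknown, collapse = ", "))
  recs <- .recordList(records)
  viable <- vapply(recs, function(r) {
    present <- lapply(r$stages, function(h) {
      if (.ENV_HOST %in% h) h else intersect(h, labels)
    })
    if (any(lengths(present) == 0L)) return(FALSE)
    if (requireTrophicSupport && length(present) > 1L) {
      for (s in seq_len(length(present) - 1L)) {
        from <- present[[s]]; to <- present[[s + 1L]]
        if (.ENV_HOST %in% from || .ENV_HOST %in% to) next
        if (r$transmission[s + 1L] != "trophic") next
        if (sum(a[to, from, drop = FALSE]) == 0L) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  keep <- names(recs)[viable]
  parasiteRecords(records@table[records@table$parasite %in% keep, ,
                                drop = FALSE])
}

#' Infer feeding links from parasite records
#'
#' A parasite found as an adult (or later stage) in a consumer implies that
#' the consumer eats the parasite's previous-stage host.  For every viable
#' parasite and every trophically acquired stage transition, each present
#' (intermediate host h, next-stage host p) pair gets the link
#' `A[p, h] = 1` if it is missing, with provenance recorded.  Links are only
#' ever added, and the operation is idempotent.
#'
#' @param web a [FoodWeb-class].
#' @param records a [ParasiteRecords-class]; filtered for viability first
#'   unless `filtered = TRUE`.
#' @param filtered set to `TRUE` if `records` already passed
#'   [filterViableParasites()].
#' @return list with elements `web` (the augmented [FoodWeb-class]) and
#'   `provenance` (data.frame consumer, resource, parasite for every link
#'   added; zero rows if nothing was missing).
#' @export
inferTrophicLinks <- function(web, records, filtered = FALSE) {
  stopifnot(is(web, "FoodWeb"), is(records, "ParasiteRecords"))
  if (!filtered)
    records <- filterViableParasites(web, records, warnUnknown = FALSE)
  labels <- speciesLabels(web)
  a <- web@adj
  prov <- list()
  recs <- .recordList(records)
  for (pn in names(recs)) {
    r <- recs[[pn]]
    if (length(r$stages) < 2L) next
    for (s in seq_len(length(r$stages) - 1L)) {
      if (r$transmission[s + 1L] != "trophic") next
      from <- intersect(r$stages[[s]], labels)
      to <- intersect(r$stages[[s + 1L]], labels)
      for (p in to) for (h in from) {
        if (a[p, h] == 0L) {
          a[p, h] <- 1L
          prov[[length(prov) + 1L]] <-
            data.frame(consumer = p, resource = h, parasite = pn,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  provenance <- if (length(prov)) do.call(rbind, prov)
    else data.frame(consumer = character(), resource = character(),
                    parasite = character(), stringsAsFactors = FALSE)
  list(web = FoodWeb(a, category = web@category), provenance = provenance)
}

#' Per-host parasite richness
#'
#' The response variable of the diversity models: for every species in the
#' web, the number of (viable) parasites that list it as a suitable host at
#' any life-cycle stage.  A parasite using a host at two stages counts once.
#' Hosts used by no parasite get richness 0 and stay in the table.
#'
#' @param web a [FoodWeb-class].
#' @param records a [ParasiteRecords-class], normally the output of
#'   [filterViableParasites()].
#' @return data.frame with columns `label`, `richness`, `parasites`
#'   (semicolon-separated parasite labels).
#' @export
hostRichness <- function(web, records) {
  stopifnot(is(web, "FoodWeb"), is(records, "ParasiteRecords"))
  labels <- speciesLabels(web)
  byHost <- lapply(stats::setNames(labels, labels), function(x) character(0))
  recs <- .recordList(records)
  for (pn in names(recs)) {
    r <- recs[[pn]]
    hosts <- intersect(unique(unlist(r$stages)), labels)
    for (h in hosts) byHost[[h]] <- c(byHost[[h]], pn)
  }
  data.frame(label = labels,
             richness = unname(lengths(byHost)),
             parasites = unname(vapply(byHost, paste, character(1),
                                       collapse = ";")),
             stringsAsFactors = FALSE)
}
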