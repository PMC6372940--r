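#' @title HTML text extraction pipelines
#' @description
#' Turn raw HTML into plain text. Two preprocessing pipelines are supported:
#' `"naive"` keeps every visible text block (only script/style content is
#' dropped), while `"boilerplate"` additionally removes blocks classified as
#' boilerplate (navigation bars, link lists, template fragments) by a
#' deterministic built-in classifier based on link-character density and
#' block length. Two sentence-ending heuristics control how blocks are glued
#' together: ForcePeriod (`"FP"`) appends a period to blocks lacking terminal
#' punctuation so each HTML field becomes its own sentence;
#' DoNotForcePeriod (`"DNFP"`) joins blocks unchanged, which can merge
#' heading and list fragments into long run-on sentences.
#' @name html_extraction
NULL

.rr_block_tags <- c("title", "h1", "h2", "h3", "h4", "h5", "h6",
                    "p", "li", "dt", "dd", "td", "th")

.rr_terminal_punct_re <- "[.!?:;]$"

.rr_kind_for_tag <- function(tag) {
  ifelse(tag %in% c("h1", "h2", "h3", "h4", "h5", "h6"), "heading",
  ifelse(tag == "p", "paragraph",
  ifelse(tag %in% c("li", "dt", "dd"), "list_item",
  ifelse(tag %in% c("td", "th"), "table_cell",
  ifelse(tag == "title", "title", "other")))))
}

.rr_squish <- function(x) trimws(gsub("[\\s ]+", " ", x, perl = TRUE))

#' Extract text blocks from an HTML page
#'
#' Parses the page (best-effort, malformed HTML never errors), drops script,
#' style and comment content, and returns the visible text grouped into
#' blocks in document order. A block is the own text of a block-level element
#' (`title`, `h1`-`h6`, `p`, `li`/`dt`/`dd`, `td`/`th`) or a run of stray
#' text outside any such element (`kind = "other"`). Under the
#' `"boilerplate"` pipeline, blocks whose link-character density exceeds
#' `link_density` or that are very short list/other fragments are removed.
#'
#' @param html a length-1 character string of (possibly malformed) HTML.
#' @param pipeline `"naive"` or `"boilerplate"`.
#' @param link_density boilerplate threshold on the fraction of characters
#'   inside `<a>` elements (default 0.5).
#' @param min_words blocks with fewer words than this and kind `list_item`
#'   or `other` are treated as boilerplate (default 5).
#' @return a data frame with columns `text`, `kind`,
#'   `ends_with_terminal_punct`, `link_density`, `n_words` and (for the
#'   naive pipeline) `boilerplate`, one row per block in document order.
#' @examples
#' extract_blocks("<p>Hello</p><p>World.</p>", "naive")
#' @export
extract_blocks <- function(html, pipeline = c("naive", "boilerplate"),
                           link_density = 0.5, min_words = 5) {
  pipeline <- match.arg(pipeline)
  empty <- data.frame(text = character(), kind = character(),
                      ends_with_terminal_punct = logical(),
                      link_density = numeric(), n_words = integer(),
                      boilerplate = logical(), stringsAsFactors = FALSE)
  if (length(html) != 1L || is.na(html) || !nzchar(trimws(html))) return(empty)
  doc <- tryCatch(xml2::read_html(html, encoding = "UTF-8"),
                  error = function(e) NULL)
  if (is.null(doc)) return(empty)
  kill <- xml2::xml_find_all(doc, "//script|//style|//noscript|//comment()")
  xml2::xml_remove(kill)
  nodes <- xml2::xml_find_all(doc, "//text()")
  if (length(nodes) == 0L) return(empty)

  txt <- xml2::xml_text(nodes)
  keep <- nzchar(trimws(txt))
  nodes <- nodes[keep]; txt <- txt[keep]
  if (length(nodes) == 0L) return(empty)

  block_xp <- paste0("ancestor-or-self::*[",
                     paste(sprintf("self::%s", .rr_block_tags), collapse = " or "),
                     "]")
  group_key <- character(length(nodes))
  group_tag <- character(length(nodes))
  in_link <- logical(length(nodes))
  for (i in seq_along(nodes)) {
    anc <- xml2::xml_find_all(nodes[[i]], block_xp)
    if (length(anc) > 0L) {
      nearest <- anc[[length(anc)]]          # document order: innermost last
      group_key[i] <- xml2::xml_path(nearest)
      group_tag[i] <- xml2::xml_name(nearest)
    } else {
      parent <- xml2::xml_parent(nodes[[i]])
      group_key[i] <- xml2::xml_path(parent)
      group_tag[i] <- "other"
    }
    in_link[i] <- !is.na(xml2::xml_find_first(nodes[[i]], "ancestor::a"))
  }
  # consecutive text nodes sharing a group key form one block
  block_id <- cumsum(c(TRUE, group_key[-1] != group_key[-length(group_key)]))
  blocks <- lapply(split(seq_along(nodes), block_id), function(ix) {
    text <- .rr_squish(paste(txt[ix], collapse = " "))
    chars <- nchar(gsub(" ", "", text, fixed = TRUE))
    link_chars <- sum(nchar(gsub("\\s+", "", txt[ix][in_link[ix]], perl = TRUE)))
    tag <- if (group_tag[ix[1]] == "other") "other" else group_tag[ix[1]]
    data.frame(
      text = text,
      kind = .rr_kind_for_tag(tag),
      ends_with_terminal_punct = grepl(.rr_terminal_punct_re, text),
      link_density = if (chars > 0) link_chars / chars else 0,
      n_words = length(regmatches(text, gregexpr("[A-Za-z0-9']+", text))[[1]]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out <- out[nzchar(out$text), , drop = FALSE]
  out$boilerplate <- out$link_density > link_density |
    (out$n_words < min_words & out$kind %in% c("list_item", "other"))
  if (pipeline == "boilerplate") {
    out <- out[!out$boilerplate, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Assemble extracted blocks into running text
#'
#' Under the ForcePeriod heuristic (`"FP"`) a period is appended to every
#' block whose trimmed text does not already end in terminal punctuation
#' (`.`, `!`, `?`, `:` or `;`); DoNotForcePeriod (`"DNFP"`) joins blocks
#' with a single space unchanged. Blocks that already end in terminal
#' punctuation are identical under both heuristics.
#'
#' @param blocks a data frame from [extract_blocks()], or a character vector
#'   of block texts.
#' @param heuristic `"FP"` or `"DNFP"`.
#' @return a single character string.
#' @examples
#' assemble_text(c("Hello", "World"), "FP")    # "Hello. World."
#' assemble_text(c("Hello", "World"), "DNFP")  # "Hello World"
#' @export
assemble_text <- function(blocks, heuristic = c("FP", "DNFP")) {
  heuristic <- match.arg(heuristic)
  texts <- if (is.data.frame(blocks)) blocks$text else as.character(blocks)
  texts <- texts[nzchar(trimws(texts))]
  if (length(texts) == 0L) return("")
  texts <- trimws(texts)
  if (heuristic == "FP") {
    lacks <- !grepl(.rr_terminal_punct_re, texts)
    texts[lacks] <- paste0(texts[lacks], ".")
  }
  paste(texts, collapse = " ")
}

#' Extract a document from raw HTML under a pipeline/heuristic setting
#'
#' Composes [extract_blocks()] and [assemble_text()]. The result records the
#' settings used; extraction is a pure function of `(html, settings)`.
#'
#' @param html raw HTML string.
#' @param doc_id non-empty document identifier.
#' @param pipeline `"naive"` or `"boilerplate"`.
#' @param heuristic `"FP"` or `"DNFP"`.
#' @inheritParams extract_blocks
#' @return an object of class `extracted_document`: a list with `doc_id`,
#'   `settings` (pipeline, heuristic), `text` and `blocks`.
#' @export
extract_document <- function(html, doc_id, pipeline = c("naive", "boilerplate"),
                             heuristic = c("FP", "DNFP"),
                             link_density = 0.5, min_words = 5) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L, nzchar(doc_id))
  pipeline <- match.arg(pipeline)
  heuristic <- match.arg(heuristic)
  blocks <- extract_blocks(html, pipeline,
                           link_density = link_density, min_words = min_words)
  structure(list(
    doc_id = doc_id,
    settings = list(pipeline = pipeline, heuristic = heuristic),
    text = assemble_text(blocks, heuristic),
    blocks = blocks
  ), class = "extracted_document")
}

#' @export
print.extracted_document <- function(x, ...) {
  cat(sprintf("<extracted_document %s: %s+%s, %d blocks, %d chars>\n",
              x$doc_id, x$settings$pipeline, x$settings$heuristic,
              nrow(x$blocks), nchar(x$text)))
  invisible(x)
}
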