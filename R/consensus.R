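#' Majority-rule direction call for one molecule
#'
#' Collapses a molecule's multi-study evidence into one direction by
#' strict majority: `up` when more than half of the voting units say
#' up, `down` when more than half say down, and `ambiguous` on an exact
#' tie (equal numbers of studies in each direction contribute no call).
#'
#' When any evidence row carries a `transcript_id`, voting is
#' two-level: each transcript first gets one vote by strict majority of
#' its own studies (transcripts that tie internally abstain), and the
#' molecule's call is then the strict majority over the transcript
#' votes. Without transcript annotation each study row is one vote.
#'
#' @param evidence Tibble of expression evidence for a single molecule
#'   (all rows share `molecule_id` and `molecule_class`).
#' @return A one-row tibble: `molecule_id`, `molecule_class`,
#'   `direction` (`up`/`down`/`ambiguous`), `n_up`, `n_down`, `n_units`
#'   (number of voting units; `n_up + n_down == n_units`).
#' @export
call_consensus <- function(evidence) {
  cx_assert(nrow(evidence) > 0, "evidence must be nonempty")
  if (dplyr::n_distinct(evidence$molecule_id) != 1 ||
      dplyr::n_distinct(evidence$molecule_class) != 1) {
    cx_abort("call_consensus: evidence mixes molecule ids or classes",
             class = "cernaxis_contract_error")
  }
  tid <- if ("transcript_id" %in% names(evidence)) evidence$transcript_id else
    rep(NA_character_, nrow(evidence))
  if (any(!is.na(tid))) {
    # inner level: one vote per transcript; untagged rows form their own unit
    key <- ifelse(is.na(tid), paste0(".row", seq_len(nrow(evidence))), tid)
    votes <- vapply(split(evidence$direction, key), majority_direction, character(1))
    votes <- votes[votes != "ambiguous"] # ties abstain at the gene level
  } else {
    votes <- evidence$direction
  }
  n_up <- sum(votes == "up")
  n_down <- sum(votes == "down")
  tibble(
    molecule_id = evidence$molecule_id[1],
    molecule_class = evidence$molecule_class[1],
    direction = majority_direction(votes),
    n_up = n_up,
    n_down = n_down,
    n_units = n_up + n_down
  )
}

majority_direction <- function(votes) {
  n_up <- sum(votes == "up")
  n_down <- sum(votes == "down")
  if (n_up > n_down) "up" else if (n_down > n_up) "down" else "ambiguous"
}

#' Consensus table over a full evidence catalog
#'
#' Applies [call_consensus()] per `(molecule_id, molecule_class)`.
#' Molecules tying at exactly 50% are retained in the table but flagged
#' `excluded`; downstream stages consume only definite up/down calls.
#' A molecule measured in several classes (e.g. as mRNA and as protein)
#' is called independently in each.
#'
#' @param evidence Tibble of expression evidence (any number of
#'   molecules and classes).
#' @return A tibble of consensus calls with an `excluded` logical
#'   column; the number of exclusions is reported as a message.
#' @export
consensus_table <- function(evidence) {
  if (is.null(evidence) || nrow(evidence) == 0) {
    warn("consensus_table: empty evidence catalog")
    return(tibble(
      molecule_id = character(0), molecule_class = character(0),
      direction = character(0), n_up = integer(0), n_down = integer(0),
      n_units = integer(0), excluded = logical(0)
    ))
  }
  if (!"transcript_id" %in% names(evidence)) evidence$transcript_id <- NA_character_
  # molecules with any transcript-tagged row take the two-level path;
  # the rest vote directly, vectorized
  tagged_ids <- unique(evidence$molecule_id[!is.na(evidence$transcript_id)])
  plain <- evidence[!evidence$molecule_id %in% tagged_ids, , drop = FALSE]
  tagged <- evidence[evidence$molecule_id %in% tagged_ids, , drop = FALSE]
  plain_calls <- plain %>%
    dplyr::group_by(.data$molecule_id, .data$molecule_class) %>%
    dplyr::summarise(n_up = sum(.data$direction == "up"),
                     n_down = sum(.data$direction == "down"),
                     .groups = "drop") %>%
    dplyr::mutate(
      n_units = .data$n_up + .data$n_down,
      direction = dplyr::case_when(.data$n_up > .data$n_down ~ "up",
                                   .data$n_down > .data$n_up ~ "down",
                                   TRUE ~ "ambiguous")
    )
  tagged_calls <- if (nrow(tagged) == 0) {
    NULL
  } else {
    tagged %>%
      dplyr::group_by(.data$molecule_id, .data$molecule_class) %>%
      dplyr::group_modify(~ call_consensus(dplyr::mutate(
        .x, molecule_id = .y$molecule_id, molecule_class = .y$molecule_class
      ))[, c("direction", "n_up", "n_down", "n_units")]) %>%
      dplyr::ungroup()
  }
  calls <- dplyr::bind_rows(plain_calls, tagged_calls) %>%
    dplyr::mutate(excluded = .data$direction == "ambiguous") %>%
    dplyr::arrange(.data$molecule_class, .data$molecule_id)
  inform(sprintf("consensus: %d molecule call(s), %d excluded as ambiguous",
                 nrow(calls), sum(calls$excluded)))
  calls
}

#' Definite direction calls only
#'
#' @param calls Output of [consensus_table()].
#' @param molecule_class Optional class filter.
#' @return Calls with `direction` in `up`/`down`.
#' @export
usable_calls <- function(calls, molecule_class = NULL) {
  out <- calls[!calls$excluded, , drop = FALSE]
  if (!is.null(molecule_class)) {
    out <- out[out$molecule_class == match_class(molecule_class), , drop = FALSE]
  }
  out
}
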