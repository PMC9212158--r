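# Thin NDEx transfer client (optional feature).  All network access goes
# through a transport function so the whole test suite runs offline with a
# mocked transport.

UUID_RE <- "^[0-9a-fA-F]{8}-[0-9a-fA-F]{4}-[0-9a-fA-F]{4}-[0-9a-fA-F]{4}-[0-9a-fA-F]{12}$"

#' NDEx credentials
#'
#' @param username Account name (`NULL` for anonymous access to public
#'   networks).
#' @param password Password or API token.
#' @param server Absolute base URL of the NDEx server.
#' @return A `ndex_credentials` object.
#' @export
ndex_credentials <- function(username = NULL, password = NULL,
                             server = "https://www.ndexbio.org") {
  if (!grepl("^https?://", server)) {
    abort("server must be an absolute http(s) URL")
  }
  structure(list(username = username, password = password, server = server),
            class = "ndex_credentials")
}

#' @export
print.ndex_credentials <- function(x, ...) {
  cat(sprintf("<ndex_credentials> %s @ %s\n", x$username %||% "<anonymous>",
              x$server))
  invisible(x)
}

# Default transport: curl over HTTPS with optional basic auth.  Signature:
# transport(verb, url, body, credentials) -> list(status, text).
ndex_transport <- function() {
  function(verb, url, body = NULL, credentials = NULL) {
    if (!requireNamespace("curl", quietly = TRUE)) {
      abort("the 'curl' package is required for live NDEx access")
    }
    h <- curl::new_handle(customrequest = verb, timeout = 60)
    if (!is.null(credentials) && !is.null(credentials$username)) {
      curl::handle_setopt(h, username = credentials$username,
                          password = credentials$password)
    }
    if (!is.null(body)) {
      curl::handle_setopt(h, postfields = body)
      curl::handle_setheaders(h, "Content-Type" = "application/json")
    }
    resp <- curl::curl_fetch_memory(url, handle = h)
    list(status = resp$status_code, text = rawToChar(resp$content))
  }
}

ndex_base <- function(credentials) {
  creds <- credentials %||% ndex_credentials()
  sub("/+$", "", creds$server)
}

ndex_check_status <- function(status, context) {
  if (status %in% c(401, 403)) {
    abort(sprintf("NDEx authorization failed (%d) while %s", status, context))
  }
  if (status == 404) {
    abort(sprintf("unknown NDEx network (404) while %s", context))
  }
  if (status >= 400) {
    abort(sprintf("NDEx server rejected the request (%d) while %s",
                  status, context))
  }
}

#' Fetch a network from NDEx by UUID
#'
#' Retrieves the CX document text of a network; credentials are only needed
#' for private networks.
#'
#' @param uuid Network UUID.
#' @param credentials Optional [ndex_credentials()].
#' @param transport Transport function (mockable);
#'   `function(verb, url, body, credentials) -> list(status, text)`.
#' @return CX document text.
#' @export
fetch_ndex <- function(uuid, credentials = NULL, transport = ndex_transport()) {
  if (!grepl(UUID_RE, uuid)) abort(sprintf("not a valid UUID: '%s'", uuid))
  url <- sprintf("%s/v2/network/%s", ndex_base(credentials), tolower(uuid))
  resp <- transport("GET", url, NULL, credentials)
  ndex_check_status(resp$status, sprintf("fetching %s", uuid))
  resp$text
}

#' Create or update a network on NDEx
#'
#' Without `uuid` a new network is created and the server-assigned UUID
#' returned; with `uuid` the existing network is updated in place.
#'
#' @param model A [cx_network()] (serialized with [serialize_cx()]).
#' @param credentials [ndex_credentials()].
#' @param uuid Optional UUID of the network to update.
#' @inheritParams fetch_ndex
#' @return The UUID of the created or updated network.
#' @export
push_ndex <- function(model, credentials, uuid = NULL,
                      transport = ndex_transport()) {
  body <- serialize_cx(model)
  base <- ndex_base(credentials)
  if (is.null(uuid)) {
    resp <- transport("POST", sprintf("%s/v2/network", base), body, credentials)
    ndex_check_status(resp$status, "creating a network")
    loc <- trimws(gsub('"', "", resp$text))
    new_uuid <- regmatches(loc, regexpr(gsub("\\^|\\$", "", UUID_RE), loc))
    if (length(new_uuid) == 0) {
      abort("NDEx create succeeded but no UUID could be read from the response")
    }
    tolower(new_uuid[[1]])
  } else {
    if (!grepl(UUID_RE, uuid)) abort(sprintf("not a valid UUID: '%s'", uuid))
    resp <- transport("PUT", sprintf("%s/v2/network/%s", base, tolower(uuid)),
                      body, credentials)
    ndex_check_status(resp$status, sprintf("updating %s", uuid))
    tolower(uuid)
  }
}
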