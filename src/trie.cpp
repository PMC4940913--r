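#include <Rcpp.h>
#include <cstring>
#include <vector>

using namespace Rcpp;

// Recursive indexing tree over DNA strings.  Nodes are kept in a flat
// vector; child slots are indexed by nucleotide (A/C/G/T).  A node may be
// both terminal and have children, which is what makes the longest-match
// policy necessary when one stored sequence is a proper prefix of another.

namespace {

struct TrieNode {
  int child[4];
  int payload;    // value attached at a terminal
  bool terminal;
  bool has_child;
  TrieNode() : payload(0), terminal(false), has_child(false) {
    child[0] = child[1] = child[2] = child[3] = -1;
  }
};

struct Trie {
  std::vector<TrieNode> nodes;
  int max_depth;
  int n_seq;
  Trie() : max_depth(0), n_seq(0) { nodes.push_back(TrieNode()); }
};

inline int base_index(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

} // namespace

// [[Rcpp::export(name = ".trie_build")]]
SEXP trie_build(CharacterVector sequences, IntegerVector payloads) {
  if (sequences.size() != payloads.size())
    stop("'sequences' and 'payloads' must have the same length");
  XPtr<Trie> tr(new Trie(), true);
  for (R_xlen_t i = 0; i < sequences.size(); ++i) {
    if (sequences[i] == NA_STRING)
      stop("sequence %d is NA", (int)(i + 1));
    if (payloads[i] == NA_INTEGER)
      stop("payload %d is NA", (int)(i + 1));
    const char* s = CHAR(STRING_ELT(sequences, i));
    int len = (int)std::strlen(s);
    if (len == 0)
      stop("sequence %d is empty", (int)(i + 1));
    int node = 0;
    for (int j = 0; j < len; ++j) {
      int b = base_index(s[j]);
      if (b < 0)
        stop("sequence %d contains a character other than A/C/G/T: '%s'",
             (int)(i + 1), s);
      int nxt = tr->nodes[node].child[b];
      if (nxt < 0) {
        nxt = (int)tr->nodes.size();
        tr->nodes.push_back(TrieNode());
        tr->nodes[node].child[b] = nxt;
        tr->nodes[node].has_child = true;
      }
      node = nxt;
    }
    if (tr->nodes[node].terminal)
      stop("duplicate sequence '%s' (stored sequences must be unique)", s);
    tr->nodes[node].terminal = true;
    tr->nodes[node].payload = payloads[i];
    if (len > tr->max_depth) tr->max_depth = len;
    tr->n_seq++;
  }
  return tr;
}

// Walk the tree from the first position of each read.  The deepest
// terminal reached wins (longest match); bases after the match are
// ignored.  'steps' counts how many read nucleotides were examined, which
// by construction never exceeds the length of the longest stored
// sequence: a node with no children is never asked for another base.
// [[Rcpp::export(name = ".trie_match")]]
List trie_match_cpp(SEXP trie_xp, CharacterVector reads) {
  XPtr<Trie> tr(trie_xp);
  R_xlen_t n = reads.size();
  IntegerVector payload(n, NA_INTEGER);
  IntegerVector consumed(n, 0);
  IntegerVector steps(n, 0);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (reads[i] == NA_STRING) continue;
    const char* r = CHAR(STRING_ELT(reads, i));
    int node = 0, depth = 0, st = 0;
    int best_payload = NA_INTEGER, best_depth = 0;
    bool found = false;
    while (true) {
      const TrieNode& nd = tr->nodes[node];
      if (nd.terminal) {
        best_payload = nd.payload;
        best_depth = depth;
        found = true;
      }
      if (!nd.has_child) break;
      char c = r[depth];
      if (c == '\0') break;
      ++st;                       // examining one read nucleotide
      int b = base_index(c);      // N (or anything non-ACGT) never matches
      if (b < 0) break;
      int nxt = nd.child[b];
      if (nxt < 0) break;
      node = nxt;
      ++depth;
    }
    if (found) payload[i] = best_payload;
    consumed[i] = best_depth;
    steps[i] = st;
  }
  return List::create(_["payload"] = payload,
                      _["consumed"] = consumed,
                      _["steps"] = steps);
}

// [[Rcpp::export(name = ".trie_depth")]]
int trie_depth_cpp(SEXP trie_xp) {
  XPtr<Trie> tr(trie_xp);
  return tr->max_depth;
}

// [[Rcpp::export(name = ".trie_size")]]
int trie_size_cpp(SEXP trie_xp) {
  XPtr<Trie> tr(trie_xp);
  return tr->n_seq;
}
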