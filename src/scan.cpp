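#include <Rcpp.h>
#include <cctype>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

// Missing-data rule: after uppercase folding, {N, ?, -} are non-variant;
// every other character is an informative allele.
static inline unsigned char fold(unsigned char c) {
  return static_cast<unsigned char>(std::toupper(c));
}

static inline bool is_missing(unsigned char c) {
  unsigned char u = fold(c);
  return u == 'N' || u == '?' || u == '-';
}

// First-pass state: one consensus character per column (0 = none seen yet)
// plus one variant flag per column -- exactly 2*g bytes of working storage.
struct ConsensusScan {
  std::vector<unsigned char> consensus;
  std::vector<unsigned char> variant;
  R_xlen_t g;
  R_xlen_t n_records;
  ConsensusScan(R_xlen_t g_) : consensus(g_, 0), variant(g_, 0), g(g_), n_records(0) {}
};

// [[Rcpp::export(name = ".scan_new")]]
SEXP scan_new(double g) {
  XPtr<ConsensusScan> p(new ConsensusScan(static_cast<R_xlen_t>(g)), true);
  return p;
}

// [[Rcpp::export(name = ".scan_add")]]
void scan_add(SEXP ptr, const std::string& seq) {
  XPtr<ConsensusScan> p(ptr);
  if (static_cast<R_xlen_t>(seq.size()) != p->g)
    stop("sequence length %d does not match alignment length %d",
         (int)seq.size(), (int)p->g);
  const unsigned char* s = reinterpret_cast<const unsigned char*>(seq.data());
  unsigned char* cons = p->consensus.data();
  unsigned char* var = p->variant.data();
  const R_xlen_t g = p->g;
  for (R_xlen_t i = 0; i < g; ++i) {
    unsigned char c = s[i];
    if (is_missing(c)) continue;
    unsigned char u = fold(c);
    if (cons[i] == 0) {
      cons[i] = u;            // first informative base seen in this column
    } else if (u != cons[i]) {
      var[i] = 1;             // second distinct informative allele
    }
  }
  p->n_records++;
}

// [[Rcpp::export(name = ".scan_sites")]]
IntegerVector scan_sites(SEXP ptr) {
  XPtr<ConsensusScan> p(ptr);
  std::vector<int> out;
  for (R_xlen_t i = 0; i < p->g; ++i)
    if (p->variant[i]) out.push_back(static_cast<int>(i));
  return wrap(out);  // 0-based, strictly increasing
}

// [[Rcpp::export(name = ".scan_consensus")]]
std::string scan_consensus(SEXP ptr) {
  XPtr<ConsensusScan> p(ptr);
  std::string out(p->g, '-');
  for (R_xlen_t i = 0; i < p->g; ++i)
    if (p->consensus[i] != 0) out[i] = static_cast<char>(p->consensus[i]);
  return out;
}

// [[Rcpp::export(name = ".scan_records")]]
double scan_records(SEXP ptr) {
  XPtr<ConsensusScan> p(ptr);
  return static_cast<double>(p->n_records);
}

// Measured first-pass auxiliary storage in characters (consensus + flags).
// [[Rcpp::export(name = ".scan_aux_chars")]]
double scan_aux_chars(SEXP ptr) {
  XPtr<ConsensusScan> p(ptr);
  return static_cast<double>(p->consensus.size() + p->variant.size());
}

// Second pass: pull the characters at the variant columns out of one
// sequence, case and gaps preserved verbatim.
// [[Rcpp::export(name = ".extract_at")]]
std::string extract_at(const std::string& seq, IntegerVector sites0) {
  std::string out(sites0.size(), ' ');
  const R_xlen_t g = static_cast<R_xlen_t>(seq.size());
  for (R_xlen_t j = 0; j < sites0.size(); ++j) {
    int i = sites0[j];
    if (i < 0 || i >= g) stop("site index %d out of range [0, %d)", i, (int)g);
    out[j] = seq[i];
  }
  return out;
}
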