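#include <Rcpp.h>
using namespace Rcpp;

// Mismatch profile of query spacers against a pre-extracted set of
// genomic protospacers (both strands, PAM-adjacent). Early exit after
// max_mm+1 mismatches keeps the scan linear in practice. An 'N' in a
// genomic site never matches any query base (conservative).
// [[Rcpp::export]]
IntegerMatrix mm_profile_cpp(CharacterVector queries, CharacterVector sites,
                             int max_mm) {
  const int nq = queries.size(), ns = sites.size();
  IntegerMatrix out(nq, max_mm + 1);
  std::vector<std::string> s(ns);
  for (int j = 0; j < ns; ++j) s[j] = as<std::string>(sites[j]);
  for (int i = 0; i < nq; ++i) {
    const std::string q = as<std::string>(queries[i]);
    const int L = (int)q.size();
    for (int j = 0; j < ns; ++j) {
      const std::string &t = s[j];
      if ((int)t.size() != L) continue;
      int mm = 0;
      for (int k = 0; k < L; ++k) {
        if (q[k] != t[k] && ++mm > max_mm) break;
      }
      if (mm <= max_mm) out(i, mm)++;
    }
  }
  return out;
}
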