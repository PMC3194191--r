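// bulk paired-read extraction for the simulator: forward mate is the first
// l bases of each fragment, reverse mate the reverse complement of the last l

#include <Rcpp.h>
#include <string>
using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'a': return 't';
    case 'c': return 'g';
    case 'g': return 'c';
    case 't': return 'a';
    default: return 'N';
  }
}

// [[Rcpp::export(name = ".extract_pairs_cpp")]]
List extract_pairs_cpp(std::string donor, IntegerVector start,
                       IntegerVector frag_len, int l) {
  const int n = start.size();
  CharacterVector s1(n), s2(n);
  std::string buf1(l, 'A'), buf2(l, 'A');
  const char* d = donor.data();
  for (int i = 0; i < n; i++) {
    const int a = start[i];
    const int b = start[i] + frag_len[i];  // fragment end (exclusive)
    for (int j = 0; j < l; j++) buf1[j] = d[a + j];
    for (int j = 0; j < l; j++) buf2[j] = comp(d[b - 1 - j]);
    s1[i] = buf1;
    s2[i] = buf2;
  }
  return List::create(_["seq1"] = s1, _["seq2"] = s2);
}
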