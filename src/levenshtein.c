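#include <R.h>
#include <Rinternals.h>
#include <string.h>

/* Vectorized Levenshtein (unit-cost insert/delete/substitute) over byte
 * strings.  Shorter argument is recycled.  NA in either slot -> NA. */
SEXP C_levenshtein(SEXP a, SEXP b)
{
    R_xlen_t na = XLENGTH(a), nb = XLENGTH(b);
    R_xlen_t n = na > nb ? na : nb;
    if (na == 0 || nb == 0)
        n = 0;
    SEXP out = PROTECT(allocVector(INTSXP, n));
    int *res = INTEGER(out);

    for (R_xlen_t i = 0; i < n; i++) {
        SEXP ea = STRING_ELT(a, i % na);
        SEXP eb = STRING_ELT(b, i % nb);
        if (ea == NA_STRING || eb == NA_STRING) {
            res[i] = NA_INTEGER;
            continue;
        }
        const char *sa = translateCharUTF8(ea);
        const char *sb = translateCharUTF8(eb);
        size_t la = strlen(sa), lb = strlen(sb);
        if (la == 0 || lb == 0) {
            res[i] = (int) (la > lb ? la : lb);
            continue;
        }
        /* two-row dynamic programme */
        int *prev = (int *) R_alloc(lb + 1, sizeof(int));
        int *cur = (int *) R_alloc(lb + 1, sizeof(int));
        for (size_t j = 0; j <= lb; j++)
            prev[j] = (int) j;
        for (size_t r = 1; r <= la; r++) {
            cur[0] = (int) r;
            for (size_t j = 1; j <= lb; j++) {
                int cost = (sa[r - 1] == sb[j - 1]) ? 0 : 1;
                int best = prev[j - 1] + cost; /* substitute / match */
                int del = prev[j] + 1;         /* delete from a */
                int ins = cur[j - 1] + 1;      /* insert into a */
                if (del < best) best = del;
                if (ins < best) best = ins;
                cur[j] = best;
            }
            int *tmp = prev;
            prev = cur;
            cur = tmp;
        }
        res[i] = prev[lb];
    }
    UNPROTECT(1);
    return out;
}
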