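entity,pattern,window_start,window_end,kind
LMU Muenchen,universit[^;]*munchen|munchen[^;]*universit|ludwig-maximilians,2006-11-01,,uoe
TU Muenchen,technische universit[^;]*munchen|tu munchen|technical universit[^;]*munich,2006-11-01,,uoe
Universitaet Karlsruhe (KIT),universit[^;]*karlsruhe|karlsruhe[^;]*universit|karlsruhe institute of technology,2006-11-01,2012-10-31,uoe
KIT (2019 line),universit[^;]*karlsruhe|karlsruhe institute of technology,2019-11-01,,uoe
RWTH Aachen,rwth|universit[^;]*aachen|aachen[^;]*universit,2007-11-01,,uoe
FU Berlin,freie universit[^;]*berlin|berlin[^;]*freie universit,2007-11-01,,uoe
HU Berlin,humboldt[- ]universit|charite,2012-11-01,,uoe
Universitaet Freiburg,universit[^;]*freiburg|freiburg[^;]*universit,2007-11-01,2012-10-31,uoe
Universitaet Goettingen,universit[^;]*gottingen|gottingen[^;]*universit|georg-august,2007-11-01,2012-10-31,uoe
Universitaet Heidelberg,universit[^;]*heidelberg|heidelberg[^;]*universit|ruprecht-karls,2007-11-01,,uoe
Universitaet Konstanz,universit[^;]*konstanz|konstanz[^;]*universit,2007-11-01,2019-10-31,uoe
Universitaet Bremen,universit[^;]*bremen|bremen[^;]*universit,2012-11-01,2019-10-31,uoe
Universitaet zu Koeln,universit[^;]*koln|koln[^;]*universit|universit[^;]*cologne|cologne[^;]*universit,2012-11-01,2019-10-31,uoe
Universitaet Tuebingen,universit[^;]*tubingen|tubingen[^;]*universit|eberhard[- ]karls,2012-11-01,,uoe
TU Dresden,technische universit[^;]*dresden|tu dresden|dresden[^;]*technische universit,2012-11-01,,uoe
Universitaet Bonn,universit[^;]*bonn|bonn[^;]*universit|rheinische friedrich-wilhelms,2019-11-01,,uoe
Universitaet Hamburg,universit[^;]*hamburg|hamburg[^;]*universit,2019-11-01,,uoe
KKS Berlin,\bberlin\b,1999-01-01,,kks
KKS Dresden,\bdresden\b,2000-01-01,,kks
KKS Duesseldorf,\bdusseldorf\b|\bduesseldorf\b,2002-01-01,,kks
KKS Essen,\bessen\b,2000-01-01,,kks
ZKS Freiburg,\bfreiburg\b,1998-01-01,,kks
KKS Halle,\bhalle\b,2005-01-01,,kks
KKS Heidelberg,\bheidelberg\b,1999-01-01,,kks
ZKS Koeln,\bkoln\b|\bcologne\b,1999-01-01,,kks
ZKS Leipzig,\bleipzig\b,2001-01-01,,kks
IZKS Mainz,\bmainz\b,2002-01-01,,kks
KKS Marburg,\bmarburg\b,1999-01-01,,kks
Muenchner Studienzentrum,\bmunchen\b|\bmunich\b,1999-01-01,,kks
ZKS Muenster,\bmunster\b,1999-01-01,,kks
ZKS Tuebingen,\btubingen\b,2009-01-01,,kks
KKS Ulm,\bulm\b,2002-01-01,,kks
ZKS Jena,\bjena\b,2004-01-01,,kks
KKS Hannover,\bhannover\b|\bhanover\b,2002-01-01,,kks
KKS Magdeburg,\bmagdeburg\b,2004-01-01,,kks
KKS Regensburg,\bregensburg\b,2004-01-01,,kks
ZKS Wuerzburg,\bwurzburg\b|\bwuerzburg\b,2007-01-01,,kks
KKS Greifswald,\bgreifswald\b,2002-01-01,,kks
KKS Hamburg,\bhamburg\b,2004-01-01,,kks
KKS Frankfurt,\bfrankfurt\b(?! ?\(oder\)),2006-01-01,,kks
KKS Mannheim,\bmannheim\b,2004-01-01,,kks
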