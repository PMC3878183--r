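contributor
coverage
creator
date
description
format
identifier
language
publisher
relation
rights
source
subject
title
type
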